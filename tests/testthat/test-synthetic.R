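test_that("the generator is deterministic and honours its configuration", {
  g1 <- generate_catalog(generator_config(seed = 5, n_indications = 12))
  g2 <- generate_catalog(generator_config(seed = 5, n_indications = 12))
  expect_identical(g1, g2)
  g3 <- generate_catalog(generator_config(seed = 6, n_indications = 12))
  expect_false(identical(g1$truth, g3$truth))

  pal <- generate_catalog(generator_config(seed = 5, n_indications = 20,
                                           curative_fraction = 0))
  expect_true(all(vapply(pal$records, function(r) r$setting,
                         character(1)) == "palliative"))
  cur <- generate_catalog(generator_config(seed = 5, n_indications = 20,
                                           curative_fraction = 1))
  expect_true(all(vapply(cur$records, function(r) r$setting,
                         character(1)) == "curative"))

  paired <- generate_catalog(generator_config(seed = 5, n_indications = 10,
                                              n_option_groups_with_alternatives = 3))
  groups <- table(vapply(paired$records, function(r) r$option_group,
                         character(1)))
  expect_equal(sum(groups == 2), 3)
})

test_that("the pipeline matches the naive ground-truth oracle", {
  g <- generate_catalog(generator_config(seed = 101, n_indications = 50))
  a <- assess_catalog(g$records)
  tr <- g$truth
  expect_equal(a$indication_id, tr$indication_id)
  for (col in c("gross_cost_usd", "comparator_cost_usd", "course_cost_usd",
                "ly_gained", "cost_per_ly_usd", "gdp_fraction",
                "annual_cost_usd")) {
    expect_equal(a[[col]], tr[[col]], tolerance = 1e-9, label = col)
  }
  expect_equal(as.character(a$category), tr$category)
  expect_equal(a$n_patients, tr$n_patients)
  expect_equal(a$excluded_conventional, tr$excluded_conventional)
})

test_that("doubling all unit prices doubles every budget total", {
  g <- generate_catalog(generator_config(seed = 33, n_indications = 30))
  base <- assess_catalog(g$records)
  doubled <- assess_catalog(scale_unit_prices(g$records, 2))
  expect_equal(doubled$annual_cost_usd, 2 * base$annual_cost_usd,
               tolerance = 1e-12)
  sel_b <- select_best_option(base[!base$excluded_conventional, ])
  sel_d <- doubled[doubled$indication_id %in% sel_b$indication_id, ]
  expect_equal(sum(sel_d$annual_cost_usd), 2 * sum(sel_b$annual_cost_usd),
               tolerance = 1e-12)
})

test_that("the published-table fixture carries verbatim values and audit flags", {
  fx <- tables_fixture()
  expect_equal(nrow(fx), 31)
  expect_equal(sum(fx$table == 1), 17)
  expect_equal(sum(fx$table == 2), 14)

  bort <- fx[fx$indication_id == "bortezomib_mm_first_line", ]
  expect_equal(bort$gain_value, 13.3)
  expect_equal(bort$course_cost_usd, 485)
  expect_equal(bort$cost_per_ly_usd, 437)

  # The consistency audit must flag at least the known printing artefacts.
  expect_gte(sum(fx$inconsistent), 2)
  expect_true(fx$inconsistent[fx$indication_id == "rituximab_follicular_maintenance"])
  expect_true(fx$inconsistent[fx$indication_id == "sunitinib_gist_second_line"])

  ctx <- attr(fx, "context")
  expect_equal(ctx$gdp_per_capita_usd, 3815)
  expect_equal(ctx$exchange_rate_lkr_per_usd, 200)
})

test_that("fixture records run through the pipeline as priced courses", {
  recs <- fixture_records(tables_fixture())
  expect_length(recs, 31)
  a <- assess_catalog(recs)
  expect_equal(nrow(a), 31)
  expect_true(all(a$assessable))
  # Priced records pass their course cost straight through.
  expect_equal(a$course_cost_usd, tables_fixture()$course_cost_usd)
})
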