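test_that("run_assessment writes a full report bundle for the published tables", {
  out <- withr::local_tempdir()
  # The published rows already passed the drug-level conventional screen,
  # so the course-cost filter is disabled when re-assessing them.
  res <- run_assessment(fixture_records(), economic_context(), out_dir = out,
                        exclusion_threshold_usd = 0)
  expect_true(file.exists(file.path(out, "league_highly_cost_effective.csv")))
  expect_true(file.exists(file.path(out, "totals.json")))
  expect_true(file.exists(file.path(out, "curve.tsv")))
  expect_true(file.exists(file.path(out, "run_log.txt")))

  # Re-assessment recomputes cost per life-year from printed course costs
  # and gains, so rows whose printed columns are inconsistent can change
  # tier; the recomputed top tier must hold exactly the rows whose
  # recomputed ratio clears the 1x GDP bound.
  fx <- tables_fixture()
  expected_top <- sort(fx$indication_id[fx$recomputed_cost_per_ly_usd < 3815])
  top <- read_league_table(file.path(out, "league_highly_cost_effective.csv"))
  expect_equal(sort(top$indication_id), expected_top)

  totals <- jsonlite::fromJSON(file.path(out, "totals.json"))
  expect_equal(totals$threshold_boundaries_usd$`1`, 3815)
  expect_equal(totals$n_records, 31)
  # Cumulative totals grow with the threshold.
  cum <- vapply(totals$cumulative_under_threshold, function(x) x$total_usd,
                numeric(1))
  expect_true(all(diff(cum) >= 0))
})

test_that("run_assessment on an empty catalog warns and writes empty reports", {
  out <- withr::local_tempdir()
  expect_warning(res <- run_assessment(list(), out_dir = out), "empty")
  expect_equal(nrow(res$assessments), 0)
  totals <- jsonlite::fromJSON(file.path(out, "totals.json"))
  expect_equal(totals$n_records, 0)
})

test_that("run_assessment totals agree with the generator's ground truth", {
  out <- withr::local_tempdir()
  g <- generate_catalog(generator_config(seed = 21, n_indications = 50))
  res <- run_assessment(g$records, out_dir = out)
  tr <- g$truth[!g$truth$excluded_conventional &
                  !is.na(g$truth$cost_per_ly_usd), ]
  tr <- tr[order(tr$cost_per_ly_usd), ]
  tr <- tr[!duplicated(tr$option_group), ]
  expect_equal(sum(res$selected$annual_cost_usd), sum(tr$annual_cost_usd),
               tolerance = 1e-9)
})

test_that("generated catalog files are deterministic and round-trip", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  run_generate(generator_config(seed = 1, n_indications = 15), f1)
  run_generate(generator_config(seed = 1, n_indications = 15), f2)
  expect_identical(readLines(f1), readLines(f2))

  run_generate(generator_config(seed = 2, n_indications = 15), f2)
  expect_false(identical(readLines(f1), readLines(f2)))

  # n_indications = 0 writes a header-only file.
  f0 <- withr::local_tempfile(fileext = ".csv")
  run_generate(generator_config(n_indications = 0,
                                n_option_groups_with_alternatives = 0), f0)
  expect_length(read_catalog(f0), 0)
  expect_equal(length(readLines(f0)), 1)

  # Re-reading a generated file reproduces the same assessments.
  recs <- read_catalog(f1)
  cfg <- generator_config(seed = 1, n_indications = 15)
  cfg$max_components <- 1L
  direct <- generate_catalog(cfg)$records
  expect_equal(assess_catalog(recs)$course_cost_usd,
               assess_catalog(direct)$course_cost_usd, tolerance = 1e-9)
})
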