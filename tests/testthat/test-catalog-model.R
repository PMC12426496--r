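test_that("domain constructors enforce their invariants", {
  expect_error(patient_profile(weight_kg = 0), class = "oncobudget_validation_error")
  expect_error(economic_context(threshold_multipliers = c(3, 1, 4)),
               class = "oncobudget_validation_error")
  expect_error(regimen_component("x", "per_kg", -1, 1, 21, unit_price = 1),
               class = "oncobudget_validation_error")
  expect_error(regimen(list(flat_component()), "curative"),
               class = "oncobudget_validation_error")  # needs planned_cycles
  expect_error(trial_evidence("DFS", 1.2, "proportion"),
               class = "oncobudget_validation_error")
  expect_error(
    indication_record("x", "d", palliative_evidence(), numeric(0),
                      regimen = regimen(list(flat_component()), "palliative")),
    class = "oncobudget_validation_error"
  )
  # Setting-dependent evidence contract: curative gains are proportions.
  expect_error(
    indication_record("x", "d", palliative_evidence(12), 10,
                      regimen = regimen(list(flat_component()), "curative",
                                        planned_cycles = 6)),
    class = "oncobudget_validation_error"
  )
})

test_that("flat CSV catalogs round-trip through write and read", {
  recs <- list(
    palliative_record("ind_a", gain = 10, estimates = c(880, 880, 880)),
    palliative_record("ind_b", gain = 20, estimates = c(40, 60))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog(recs, path)
  back <- read_catalog(path)
  expect_length(back, 2)
  expect_length(back[[1]]$patient_estimates, 3)
  expect_equal(back[[1]]$patient_estimates, c(880, 880, 880))
  a1 <- assess_catalog(recs)
  a2 <- assess_catalog(back)
  expect_equal(a2$course_cost_usd, a1$course_cost_usd, tolerance = 1e-12)
  expect_equal(a2$annual_cost_usd, a1$annual_cost_usd, tolerance = 1e-12)
})

test_that("catalog reader reports schema and validation problems precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  tpl <- catalog_template()
  readr::write_csv(tpl[, setdiff(names(tpl), "unit_price")], path, na = "")
  expect_error(read_catalog(path), "unit_price",
               class = "oncobudget_schema_error")

  # Header-only file is an empty catalog, not an error.
  readr::write_csv(catalog_template(), path, na = "")
  expect_length(read_catalog(path), 0)

  # A negative dose is rejected with the offending row index.
  recs <- list(palliative_record("ind_bad"))
  write_catalog(recs, path)
  txt <- readr::read_csv(path, show_col_types = FALSE)
  txt$dose_value_mg[1] <- -5
  readr::write_csv(txt, path, na = "")
  expect_error(read_catalog(path), "row 1")
})

test_that("league tables sort by GDP fraction within category and round-trip", {
  fx <- tables_fixture()
  a <- fixture_assessments(fx, use = "published")
  path <- withr::local_tempfile(fileext = ".csv")
  write_league_table(a, path)
  back <- read_league_table(path)
  expect_equal(nrow(back), 31)
  # First palliative entry of the top tier is rituximab maintenance at 0.06.
  top <- back[back$category == "highly_cost_effective", ]
  expect_equal(top$indication_id[1], "rituximab_follicular_maintenance")
  expect_equal(top$gdp_fraction[1], 0.06)
  # Numeric fields survive the round trip at reporting precision.
  expect_equal(back$course_cost_usd,
               round_half_up(a[order(a$category, a$gdp_fraction, a$drug_name), ]$course_cost_usd, 2))

  # Ties on gdp_fraction break alphabetically by drug name.
  two <- a[1:2, ]
  two$gdp_fraction <- 0.5
  two$category <- factor("cost_effective",
                         levels = levels(a$category), ordered = TRUE)
  two$drug_name <- c("zeta", "alpha")
  write_league_table(two, path)
  expect_equal(read_league_table(path)$drug_name, c("alpha", "zeta"))

  # Single assessment gives a single-row file.
  write_league_table(a[1, ], path)
  expect_equal(nrow(read_league_table(path)), 1)
  expect_error(write_league_table(a[0, ], path),
               class = "oncobudget_validation_error")
})

test_that("economic context files load from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gdp_per_capita_usd: 3815", "exchange_rate: 200",
               "life_expectancy_years: 77", "multipliers: [1, 3, 4]",
               "reference_year: 2021"), yml)
  ctx <- read_economic_context(yml)
  expect_s3_class(ctx, "economic_context")
  expect_equal(ctx$threshold_multipliers, c(1, 3, 4))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(gdp_per_capita_usd = 1000, exchange_rate = 50,
                            life_expectancy_years = 70,
                            multipliers = c(1, 2, 3)),
                       js, auto_unbox = TRUE)
  ctx2 <- read_economic_context(js)
  expect_equal(ctx2$gdp_per_capita_usd, 1000)
})
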