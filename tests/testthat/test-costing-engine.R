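test_that("dose per administration follows the dosing rule", {
  prof <- patient_profile()  # 50 kg, 1.3 m2 reference adult
  flat <- regimen_component("a", "flat_per_admin", 1000, 1, 21, unit_price = 1)
  perkg <- regimen_component("b", "per_kg", 6, 1, 21, unit_price = 1)
  perm2 <- regimen_component("c", "per_m2", 175, 1, 21, unit_price = 1)
  expect_equal(dose_per_administration(flat, prof), 1000)
  expect_equal(dose_per_administration(perkg, prof), 300)   # 6 x 50
  expect_equal(dose_per_administration(perm2, prof), 227.5) # 175 x 1.3
  expect_error(dose_per_administration(list(), prof),
               class = "oncobudget_config_error")
})

test_that("currency conversion divides by the exchange rate", {
  ctx <- economic_context()
  expect_equal(convert_to_usd(200, ctx), 1)
  expect_equal(convert_to_usd(0, ctx), 0)
  expect_equal(convert_to_usd(756000, ctx), 3780)
  expect_error(convert_to_usd(1, list(exchange_rate_lkr_per_usd = -1)),
               class = "oncobudget_config_error")
})

test_that("palliative exposure prefers treatment duration, then PFS", {
  expect_equal(palliative_exposure_months(
    trial_evidence("OS", 10, "months", median_tx_months = 13.3,
                   median_pfs_months = 5)), 13.3)
  expect_equal(palliative_exposure_months(
    trial_evidence("PFS", 5.4, "months", median_pfs_months = 5.4)), 5.4)
  expect_error(palliative_exposure_months(trial_evidence("OS", 10, "months")),
               class = "oncobudget_evidence_error")
})

test_that("course costs follow protocol cycles, exposure and comparator rules", {
  prof <- patient_profile()
  ctx <- economic_context()
  # Curative: 100 mg x 1 USD/mg x 1 admin/cycle x 6 cycles = 600 USD.
  cur <- regimen(list(flat_component(1)), "curative", planned_cycles = 6)
  ev <- curative_evidence()
  cc <- course_cost(cur, ev, prof, ctx)
  expect_equal(cc$gross_usd, 600)
  expect_equal(cc$net_usd, 600)

  # Substitutive: comparator priced over the same schedule and subtracted.
  cheap <- regimen(list(flat_component(1, dose_mg = 100 / 6)), "curative",
                   planned_cycles = 6)
  sub <- regimen(list(flat_component(1)), "curative", planned_cycles = 6,
                 comparator = cheap)
  cc2 <- course_cost(sub, ev, prof, ctx)
  expect_equal(cc2$comparator_usd, 100, tolerance = 1e-12)
  expect_equal(cc2$net_usd, 500, tolerance = 1e-12)

  # Additive: net equals gross no matter the comparator.
  add <- regimen(list(flat_component(1)), "curative", planned_cycles = 6,
                 additive = TRUE, comparator = cheap)
  cc3 <- course_cost(add, ev, prof, ctx)
  expect_equal(cc3$net_usd, cc3$gross_usd)
  expect_equal(cc3$comparator_usd, 0)

  # Palliative exposure: a started cycle is dispensed in full.
  pal <- regimen(list(flat_component(1, cycle_days = 21)), "palliative")
  cc4 <- course_cost(pal, palliative_evidence(gain_months = 3, tx_months = 3),
                     prof, ctx)
  expect_equal(cc4$gross_usd, 100 * ceiling(3 * 30.44 / 21))
})

test_that("the conventional-drug filter excludes strictly below 1000 USD", {
  expect_true(is_conventional_excluded(180))   # imatinib-like annual cost
  expect_false(is_conventional_excluded(1000)) # boundary stays included
  expect_false(is_conventional_excluded(1502))
  expect_true(is_conventional_excluded(999.999))
})

test_that("horizon excess cost is the annual difference times the horizon", {
  expect_equal(horizon_excess_cost(100, 100, 10), 0)
  expect_equal(horizon_excess_cost(5480, 180, 10), 53000)
  expect_equal(horizon_excess_cost(1000, 0, 3), 3000)
  expect_error(horizon_excess_cost(1, 1, 0),
               class = "oncobudget_validation_error")
})

test_that("course costs are homogeneous in prices and monotone in exposure", {
  g <- generate_catalog(generator_config(seed = 11, n_indications = 15))
  a1 <- assess_catalog(g$records)
  a2 <- assess_catalog(scale_unit_prices(g$records, 3))
  expect_equal(a2$gross_cost_usd, 3 * a1$gross_cost_usd, tolerance = 1e-12)
  expect_equal(a2$comparator_cost_usd, 3 * a1$comparator_cost_usd,
               tolerance = 1e-12)
  expect_equal(a2$course_cost_usd, 3 * a1$course_cost_usd, tolerance = 1e-12)

  pal <- regimen(list(flat_component(1)), "palliative")
  costs <- vapply(seq(1, 36, by = 0.7), function(m) {
    course_cost(pal, palliative_evidence(gain_months = m, tx_months = m))$gross_usd
  }, numeric(1))
  expect_true(all(diff(costs) >= 0))
})
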