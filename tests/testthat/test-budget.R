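test_that("patient numbers are the expert mean, rounded half-up", {
  expect_equal(estimate_patients(c(880, 880, 880)), 880L)
  expect_equal(estimate_patients(c(400, 500, 600)), 500L)
  expect_equal(estimate_patients(c(100, 101)), 101L)  # 100.5 rounds up
  expect_error(estimate_patients(numeric(0)),
               class = "oncobudget_validation_error")
})

test_that("annual indication cost multiplies net course cost by patients", {
  expect_equal(annual_indication_cost(5619, 100), 561900)
  expect_equal(annual_indication_cost(7780, 100), 778000)
  expect_equal(annual_indication_cost(12345, 0), 0)
})

test_that("best-option selection keeps the cheapest per life-year in each group", {
  a <- fixture_assessments(tables_fixture(), use = "published")
  sel <- select_best_option(a)
  expect_equal(nrow(sel), dplyr::n_distinct(a$option_group))
  expect_true("trastuzumab_adjuvant_6mo" %in% sel$indication_id)
  expect_false("trastuzumab_adjuvant_12mo" %in% sel$indication_id)
  expect_true("sunitinib_mrcc_first_line" %in% sel$indication_id)
  expect_false("pazopanib_mrcc_first_line" %in% sel$indication_id)
  # Selection crosses tier boundaries: the dearer pre-docetaxel abiraterone
  # schedule sits in the second tier but loses to the cheap one in the first.
  expect_false("abiraterone_1000_crpc_pre_docetaxel" %in% sel$indication_id)
  # Singleton groups select themselves.
  expect_true("topotecan_cervix_second_line" %in% sel$indication_id)
  # Invariant to input order.
  set.seed(1)
  sel2 <- select_best_option(a[sample(nrow(a)), ])
  expect_equal(sel2, sel)
})

test_that("threshold-capped totals are cumulative and monotone", {
  a <- fixture_assessments(tables_fixture(), use = "published")
  sel <- select_best_option(a)
  scheme <- threshold_scheme(economic_context())
  totals <- vapply(scheme$labels, total_under_threshold,
                   numeric(1), assessments = sel, scheme = scheme)
  expect_true(all(diff(totals) >= 0))
  expect_equal(unname(totals["cost_effective"] - totals["highly_cost_effective"]),
               7209904)
  expect_equal(total_under_threshold(sel[0, ]), 0)
})

test_that("the affordability curve is ordered, cumulative and order-invariant", {
  a <- fixture_assessments(tables_fixture(), use = "published")
  sel <- select_best_option(a)
  curve <- cumulative_curve(sel)
  pts <- curve$points
  expect_equal(pts$indication_id[1], "rituximab_follicular_maintenance")
  expect_equal(pts$gdp_fraction[1], 0.06)
  expect_true(!is.unsorted(pts$gdp_fraction))
  expect_true(all(diff(pts$cumulative_annual_cost_usd) >= 0))
  # Last point carries the unconstrained total of the selected options.
  expect_equal(pts$cumulative_annual_cost_usd[nrow(pts)],
               sum(sel$annual_cost_usd))
  # Permutation invariance.
  set.seed(2)
  curve2 <- cumulative_curve(sel[sample(nrow(sel)), ])
  expect_equal(curve2$points, pts)
  # Single assessment: one point equal to its own annual cost.
  single <- cumulative_curve(sel[1, ])
  expect_equal(nrow(single$points), 1)
  expect_equal(single$points$cumulative_annual_cost_usd,
               sel$annual_cost_usd[1])
})

test_that("the curve plot builds without error", {
  sel <- select_best_option(fixture_assessments(tables_fixture()))
  p <- plot_budget_curve(cumulative_curve(sel))
  expect_s3_class(p, "ggplot")
})
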