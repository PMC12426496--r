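# Course costing: dose arithmetic, currency conversion, exposure mapping,
# comparator subtraction, the conventional-drug exclusion filter, and
# fixed-horizon excess costs for chronic therapies.

#' Drug quantity per administration
#'
#' Applies the component's dose rule to the reference patient:
#' `flat_per_admin` returns the dose as-is, `per_kg` multiplies by body
#' weight and `per_m2` by body surface area.
#'
#' @param component A [regimen_component()].
#' @param profile A [patient_profile()].
#' @return Dose in mg for one administration.
#' @examples
#' dose_per_administration(
#'   regimen_component("trastuzumab", "per_kg", 6, 1, 21, unit_price = 50),
#'   patient_profile()
#' )
#' @export
dose_per_administration <- function(component, profile = patient_profile()) {
  if (!inherits(component, "regimen_component")) {
    abort("`component` must be a regimen_component.",
          class = "oncobudget_config_error")
  }
  switch(component$dose_rule,
    flat_per_admin = component$dose_value_mg,
    per_kg = component$dose_value_mg * profile$weight_kg,
    per_m2 = component$dose_value_mg * profile$body_surface_area_m2,
    abort(sprintf("Unknown dose rule '%s'.", component$dose_rule),
          class = "oncobudget_config_error")
  )
}

#' Convert a local-currency amount to USD
#'
#' @param amount_lkr Amount in local currency (LKR in the reference case).
#' @param ctx An [economic_context()].
#' @return Amount in USD.
#' @examples
#' convert_to_usd(756000, economic_context())  # 3780
#' @export
convert_to_usd <- function(amount_lkr, ctx) {
  if (!inherits(ctx, "economic_context") || ctx$exchange_rate_lkr_per_usd <= 0) {
    abort("`ctx` must be an economic_context with a positive exchange rate.",
          class = "oncobudget_config_error")
  }
  amount_lkr / ctx$exchange_rate_lkr_per_usd
}

component_unit_price_usd <- function(component, ctx) {
  if (component$currency == "USD") component$unit_price
  else convert_to_usd(component$unit_price, ctx)
}

#' Treatment exposure for a palliative regimen
#'
#' Palliative treatment typically continues until progression, so exposure is
#' the trial's median treatment duration when reported, otherwise the median
#' progression-free survival stands in for it.
#'
#' @param evidence A [trial_evidence()].
#' @return Exposure in months.
#' @export
palliative_exposure_months <- function(evidence) {
  if (!is.null(evidence$median_tx_months)) return(evidence$median_tx_months)
  if (!is.null(evidence$median_pfs_months)) return(evidence$median_pfs_months)
  abort("Evidence reports neither median treatment duration nor median PFS; palliative exposure is underivable.",
        class = "oncobudget_evidence_error")
}

# A started cycle is dispensed in full, hence the ceiling.
administrations_for_exposure <- function(exposure_months, cycle_days,
                                         admins_per_cycle) {
  ceiling(exposure_months * DAYS_PER_MONTH / cycle_days) * admins_per_cycle
}

price_regimen_usd <- function(reg, exposure_months, profile, ctx) {
  total <- 0
  for (comp in reg$components) {
    n_admins <- if (reg$setting == "curative") {
      reg$planned_cycles * comp$admins_per_cycle
    } else {
      administrations_for_exposure(exposure_months, comp$cycle_days,
                                   comp$admins_per_cycle)
    }
    total <- total +
      dose_per_administration(comp, profile) *
      component_unit_price_usd(comp, ctx) * n_admins
  }
  total
}

#' Price a full treatment course
#'
#' Gross cost is the sum over components of dose x unit price x number of
#' administrations: over the protocol-fixed `planned_cycles` in the curative
#' setting, or over the trial-derived exposure (mapped to whole cycles with a
#' ceiling, since a started cycle is dispensed) in the palliative setting.
#' For substitutive regimens the comparator arm is priced over the same
#' exposure at its own cadence and subtracted; additive regimens keep the
#' full gross cost.
#'
#' @param regimen A [regimen()].
#' @param evidence A [trial_evidence()] (supplies palliative exposure).
#' @param profile A [patient_profile()].
#' @param ctx An [economic_context()].
#' @return An object of class `course_cost` with elements `gross_usd`,
#'   `comparator_usd`, `net_usd`, `exposure_months` (palliative) or
#'   `n_cycles_used` (curative), and `negative_net` flag.
#' @export
course_cost <- function(regimen, evidence, profile = patient_profile(),
                        ctx = economic_context()) {
  exposure_months <- NULL
  if (regimen$setting == "palliative") {
    exposure_months <- palliative_exposure_months(evidence)
  } else if (is.null(regimen$planned_cycles)) {
    abort("Curative costing needs `planned_cycles`.",
          class = "oncobudget_config_error")
  }
  gross <- price_regimen_usd(regimen, exposure_months, profile, ctx)
  comparator_usd <- 0
  if (!regimen$additive && !is.null(regimen$comparator)) {
    cmp <- regimen$comparator
    if (cmp$setting == "curative" && is.null(cmp$planned_cycles)) {
      # Comparator protocols without their own cycle count mirror the novel
      # regimen's duration.
      cmp$planned_cycles <- regimen$planned_cycles
    }
    comparator_usd <- price_regimen_usd(cmp, exposure_months, profile, ctx)
  }
  net <- if (regimen$additive) gross else gross - comparator_usd
  structure(
    list(
      gross_usd = gross,
      comparator_usd = if (regimen$additive) 0 else comparator_usd,
      net_usd = net,
      exposure_months = exposure_months,
      n_cycles_used = regimen$planned_cycles,
      negative_net = net < 0
    ),
    class = "course_cost"
  )
}

as_net_usd <- function(course) {
  if (inherits(course, "course_cost")) course$net_usd
  else if (is_scalar_number(course)) course
  else abort("Expected a course_cost or a numeric net cost in USD.",
             class = "oncobudget_validation_error")
}

#' Conventional-drug exclusion filter
#'
#' The analysis targets novel therapeutics; conventional agents whose whole
#' course costs less than US$1,000 are excluded.  The bound is strict: a
#' course costing exactly the threshold stays in.
#'
#' @param course A `course_cost` or numeric net cost in USD.
#' @param threshold_usd Exclusion threshold (default 1000).
#' @return `TRUE` if the course is excluded as conventional.
#' @export
is_conventional_excluded <- function(course, threshold_usd = 1000) {
  as_net_usd(course) < threshold_usd
}

#' Fixed-horizon excess cost of a chronic therapy
#'
#' For chronic treatments (such as tyrosine-kinase inhibitors in chronic
#' myeloid leukaemia) where trial follow-up is too short to estimate a
#' survival gain, the drug's affordability is summarised as its cost above
#' the comparator over a fixed horizon.
#'
#' @param annual_novel_usd Annual cost of the novel agent, US$/year.
#' @param annual_comparator_usd Annual cost of the comparator, US$/year.
#' @param horizon_years Horizon in years (> 0).
#' @return `(annual_novel_usd - annual_comparator_usd) * horizon_years`.
#' @examples
#' horizon_excess_cost(5480, 180, 10)  # 53000
#' @export
horizon_excess_cost <- function(annual_novel_usd, annual_comparator_usd,
                                horizon_years) {
  check_positive_scalar(horizon_years, "horizon_years")
  (annual_novel_usd - annual_comparator_usd) * horizon_years
}
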