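# End-to-end assessment: catalog records -> one league-table row each.

#' Assess every indication in a catalog
#'
#' Runs the full pipeline per record: course costing (or the record's
#' pre-priced course cost), life-years gained, cost per life-year, GDP
#' fraction, threshold category, consensus patient numbers and annual
#' national cost.  Records are never dropped: the conventional-drug
#' exclusion and undefined cost-per-life-year cases are flagged in the
#' `excluded_conventional` and `assessable` columns, and summarised in the
#' `"log"` attribute, so callers decide what to filter.
#'
#' @param records List of [indication_record()] objects.
#' @param ctx An [economic_context()].
#' @param profile A [patient_profile()].
#' @param exclusion_threshold_usd Conventional-drug exclusion bound
#'   (strict `<`, default 1000).
#' @return A tibble with one row per record: `indication_id`,
#'   `option_group`, `drug_name`, `setting`, `basis`, `gain_value`,
#'   `gain_unit`, `gross_cost_usd`, `comparator_cost_usd`,
#'   `course_cost_usd` (net), `ly_gained`, `cost_per_ly_usd`,
#'   `gdp_fraction`, `category`, `n_patients`, `annual_cost_usd`,
#'   `excluded_conventional`, `assessable`.
#' @export
assess_catalog <- function(records, ctx = economic_context(),
                           profile = patient_profile(),
                           exclusion_threshold_usd = 1000) {
  scheme <- threshold_scheme(ctx)
  log_lines <- character(0)
  rows <- lapply(records, function(rec) {
    if (!inherits(rec, "indication_record")) {
      abort("`records` must be indication_record objects.",
            class = "oncobudget_validation_error")
    }
    if (!is.null(rec$regimen)) {
      cc <- course_cost(rec$regimen, rec$evidence, profile, ctx)
      gross <- cc$gross_usd
      comparator <- cc$comparator_usd
      net <- cc$net_usd
      if (cc$negative_net) {
        log_lines <<- c(log_lines, sprintf(
          "[%s] net course cost is negative (comparator dearer than novel agent).",
          rec$indication_id))
      }
    } else {
      gross <- rec$course_cost_usd
      comparator <- 0
      net <- rec$course_cost_usd
    }
    excluded <- is_conventional_excluded(net, exclusion_threshold_usd)
    if (excluded) {
      log_lines <<- c(log_lines, sprintf(
        "[%s] excluded as conventional: net course cost %.2f USD < %.0f USD.",
        rec$indication_id, net, exclusion_threshold_usd))
    }
    gain <- life_years_gained(rec$evidence, rec$setting, ctx)
    clyg <- tryCatch(cost_per_ly(net, gain), oncobudget_undefined_icer = function(e) {
      log_lines <<- c(log_lines, sprintf(
        "[%s] not assessable: life-year gain is not positive.", rec$indication_id))
      NA_real_
    })
    n <- estimate_patients(rec$patient_estimates)
    tibble(
      indication_id = rec$indication_id,
      option_group = rec$option_group,
      drug_name = rec$drug_name,
      setting = rec$setting,
      basis = gain$basis,
      gain_value = rec$evidence$gain_value,
      gain_unit = rec$evidence$gain_unit,
      gross_cost_usd = gross,
      comparator_cost_usd = comparator,
      course_cost_usd = net,
      ly_gained = gain$years,
      cost_per_ly_usd = clyg,
      gdp_fraction = gdp_fraction(clyg, ctx),
      n_patients = n,
      annual_cost_usd = annual_indication_cost(net, n),
      excluded_conventional = excluded,
      assessable = !is.na(clyg)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      indication_id = character(0), option_group = character(0),
      drug_name = character(0), setting = character(0), basis = character(0),
      gain_value = numeric(0), gain_unit = character(0),
      gross_cost_usd = numeric(0), comparator_cost_usd = numeric(0),
      course_cost_usd = numeric(0), ly_gained = numeric(0),
      cost_per_ly_usd = numeric(0), gdp_fraction = numeric(0),
      n_patients = integer(0), annual_cost_usd = numeric(0),
      excluded_conventional = logical(0), assessable = logical(0)
    )
  }
  out$category <- classify_cost_effectiveness(out$cost_per_ly_usd, scheme)
  out <- dplyr::relocate(out, "category", .after = "gdp_fraction")
  attr(out, "log") <- log_lines
  out
}
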