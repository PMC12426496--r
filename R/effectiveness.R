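# Converting trial survival evidence into life-years gained.

LY_BASES <- c("median_OS", "median_PFS", "RMST", "DFS_extrapolated",
              "OS_extrapolated")

life_year_gain <- function(years, basis, residual_years_used = NA_real_) {
  check_non_negative_scalar(years, "years")
  basis <- match.arg(basis, LY_BASES)
  structure(
    list(years = years, basis = basis,
         residual_years_used = residual_years_used),
    class = "life_year_gain"
  )
}

#' Choose the survival basis for an indication
#'
#' Palliative: restricted mean survival time when reported (more robust than
#' medians for long-tailed curves), otherwise median OS, otherwise median PFS
#' -- the usable measure when control-arm crossover dilutes the OS difference
#' or OS is unavailable.  Curative: mature OS when reported, otherwise the
#' disease-free (or disease-specific) survival gain is substituted and
#' extrapolated.
#'
#' @param evidence A [trial_evidence()].
#' @param setting `"curative"` or `"palliative"`.
#' @return A basis label: one of `"median_OS"`, `"median_PFS"`, `"RMST"`,
#'   `"DFS_extrapolated"`, `"OS_extrapolated"`.
#' @export
select_outcome_basis <- function(evidence, setting) {
  setting <- match.arg(setting, SETTINGS)
  m <- evidence$outcome_measure
  if (setting == "palliative") {
    if (m == "RMST") return("RMST")
    if (m == "OS") return("median_OS")
    if (m == "PFS") return("median_PFS")
    abort(sprintf("No usable palliative survival measure (got %s).", m),
          class = "oncobudget_evidence_error")
  }
  if (m == "OS") return("OS_extrapolated")
  if (m %in% c("DFS", "DSS")) return("DFS_extrapolated")
  abort(sprintf("No usable curative survival measure (got %s).", m),
        class = "oncobudget_evidence_error")
}

#' Life-years gained in the palliative setting
#'
#' A median (or restricted-mean) survival gain in months translates directly
#' into life-years.
#'
#' @param gain_months Survival gain in months (>= 0).
#' @param basis Basis label recorded for audit.
#' @return A `life_year_gain` with `years = gain_months / 12`.
#' @examples
#' ly_palliative(16.8)$years  # 1.4
#' @export
ly_palliative <- function(gain_months, basis = "median_OS") {
  check_non_negative_scalar(gain_months, "gain_months")
  life_year_gain(gain_months / MONTHS_PER_YEAR, basis)
}

#' Residual life expectancy beyond trial follow-up
#'
#' The curative extrapolation assumes survivors at the end of trial follow-up
#' live on to the population life expectancy, so each percentage point of
#' survival gain is worth the years remaining between end of follow-up and
#' life expectancy: `max(0, life_expectancy - age_at_diagnosis - follow_up)`.
#'
#' @param ctx An [economic_context()] (supplies life expectancy).
#' @param evidence A [trial_evidence()] with `age_dx_years` and
#'   `follow_up_years`.
#' @return Residual years (floored at zero).
#' @export
residual_life_years <- function(ctx, evidence) {
  if (is.null(evidence$age_dx_years) || is.null(evidence$follow_up_years)) {
    abort("Curative extrapolation needs age at diagnosis and follow-up years.",
          class = "oncobudget_evidence_error")
  }
  max(0, ctx$life_expectancy_years - evidence$age_dx_years -
        evidence$follow_up_years)
}

#' Life-years gained in the curative setting
#'
#' The absolute survival-proportion gain at end of follow-up, times the
#' residual life expectancy of a survivor: undiscounted, as is conventional
#' for this style of rapid league-table screening.
#'
#' @param delta_survival Absolute survival-proportion gain in `[0, 1]`.
#' @param residual_years Residual life expectancy (see
#'   [residual_life_years()]).
#' @param basis Basis label recorded for audit.
#' @return A `life_year_gain` with `years = delta_survival * residual_years`.
#' @examples
#' ly_curative(0.065, 20)$years  # 1.3
#' @export
ly_curative <- function(delta_survival, residual_years,
                        basis = "DFS_extrapolated") {
  if (!is_scalar_number(delta_survival) || delta_survival < 0 ||
      delta_survival > 1) {
    abort("`delta_survival` must lie in [0, 1].",
          class = "oncobudget_validation_error")
  }
  check_non_negative_scalar(residual_years, "residual_years")
  life_year_gain(delta_survival * residual_years, basis,
                 residual_years_used = residual_years)
}

#' Life-years gained for one indication
#'
#' Dispatches on setting: palliative gains in months are divided by 12;
#' curative proportion gains are multiplied by the residual life expectancy.
#'
#' @param evidence A [trial_evidence()].
#' @param setting `"curative"` or `"palliative"`.
#' @param ctx An [economic_context()].
#' @return A `life_year_gain`.
#' @export
life_years_gained <- function(evidence, setting, ctx = economic_context()) {
  basis <- select_outcome_basis(evidence, setting)
  if (setting == "palliative") {
    ly_palliative(evidence$gain_value, basis = basis)
  } else {
    ly_curative(evidence$gain_value, residual_life_years(ctx, evidence),
                basis = basis)
  }
}
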