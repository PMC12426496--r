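# Cost per life-year gained, GDP fractions and WHO threshold classification.

CATEGORY_LEVELS <- c("highly_cost_effective", "cost_effective",
                     "potentially_cost_effective", "not_cost_effective")

#' WHO GDP-multiple threshold scheme
#'
#' Builds the category boundaries from the context's GDP multipliers: with
#' the default multipliers 1 / 3 / 4 and a per-capita GDP of US$3,815 the
#' boundaries are 3,815 / 11,445 / 15,260 US$ per life-year gained, and the
#' four categories are highly cost-effective (< 1x GDP), cost-effective
#' (1-3x), potentially cost-effective with price reduction (3-4x) and not
#' cost-effective (> 4x).
#'
#' @param ctx An [economic_context()].
#' @param labels Category labels; length must be
#'   `length(threshold_multipliers) + 1`.
#' @return An object of class `threshold_scheme` with `boundaries` (named by
#'   multiplier) and `labels`.
#' @examples
#' threshold_scheme(economic_context())$boundaries
#' @export
threshold_scheme <- function(ctx = economic_context(),
                             labels = CATEGORY_LEVELS) {
  boundaries <- ctx$threshold_multipliers * ctx$gdp_per_capita_usd
  if (length(labels) != length(boundaries) + 1) {
    abort("Need exactly one more category label than boundaries.",
          class = "oncobudget_validation_error")
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    abort("Threshold boundaries must be strictly increasing.",
          class = "oncobudget_validation_error")
  }
  structure(
    list(boundaries = stats::setNames(boundaries, ctx$threshold_multipliers),
         labels = labels),
    class = "threshold_scheme"
  )
}

#' Cost per life-year gained
#'
#' The league table's ranking statistic: net course cost divided by
#' life-years gained.  A zero (or negative) gain leaves the ratio undefined;
#' this is reported as a classed error so callers can mark the indication
#' not assessable rather than propagate an infinity.
#'
#' @param course A `course_cost` (see [course_cost()]) or numeric net USD.
#' @param gain A `life_year_gain` or numeric years (> 0).
#' @return US$ per life-year gained (unrounded).
#' @examples
#' cost_per_ly(945, 1.4)  # 675
#' @export
cost_per_ly <- function(course, gain) {
  years <- if (inherits(gain, "life_year_gain")) gain$years else gain
  if (!is_scalar_number(years) || years <= 0) {
    abort("Life-year gain is not positive; cost per life-year is undefined (not assessable).",
          class = "oncobudget_undefined_icer")
  }
  as_net_usd(course) / years
}

#' Cost per life-year as a fraction of per-capita GDP
#'
#' @param clyg Cost per life-year gained, US$ (vectorised).
#' @param ctx An [economic_context()].
#' @return `clyg / gdp_per_capita_usd`, unrounded (report at 2 dp).
#' @examples
#' gdp_fraction(675, economic_context())  # 0.1769...
#' @export
gdp_fraction <- function(clyg, ctx = economic_context()) {
  clyg / ctx$gdp_per_capita_usd
}

#' Classify cost per life-year against the threshold scheme
#'
#' Boundary convention: the first boundary (1x GDP) is exclusive for the
#' highly-cost-effective band ("less than per-capita GDP"); later boundaries
#' are inclusive for their lower band (a ratio of exactly 3x GDP is
#' cost-effective).
#'
#' @param clyg Cost per life-year gained, US$ (vectorised; `NA` passes
#'   through).
#' @param scheme A [threshold_scheme()].
#' @return An ordered factor over the scheme's labels.
#' @examples
#' classify_cost_effectiveness(c(675, 4816, 12000, 20000))
#' @export
classify_cost_effectiveness <- function(clyg, scheme = threshold_scheme()) {
  b <- scheme$boundaries
  idx <- vapply(clyg, function(x) {
    if (is.na(x)) return(NA_integer_)
    if (x < b[[1]]) return(1L)
    for (k in seq_along(b)[-1]) if (x <= b[[k]]) return(k)
    length(b) + 1L
  }, integer(1))
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Cost per life-year of a de-escalated treatment
#'
#' De-escalated schedules proven non-inferior (a quarter-dose of abiraterone
#' with food; six rather than twelve months of adjuvant trastuzumab) are
#' assumed to deliver the standard schedule's survival gain, so their cost is
#' divided by the *standard* treatment's life-years gained.  Both options are
#' kept as separate assessments within the same option group.
#'
#' @param deesc_course `course_cost` or numeric net USD of the de-escalated
#'   schedule.
#' @param standard_gain `life_year_gain` (or numeric years) of the standard
#'   schedule.
#' @return US$ per life-year gained.
#' @examples
#' assess_deescalation(1502, 1.3)  # 1155.38...
#' @export
assess_deescalation <- function(deesc_course, standard_gain) {
  cost_per_ly(deesc_course, standard_gain)
}
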