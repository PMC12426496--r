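# Patient-number estimation, annual indication costs, best-option selection,
# threshold-capped totals and the cumulative affordability curve.

#' Consensus patient count from expert estimates
#'
#' National registries rarely record stage distribution or treatment line, so
#' annual patient numbers per indication come from independent expert
#' estimates; the arithmetic mean is used, rounded half-up to a whole
#' patient.
#'
#' @param estimates Non-empty vector of non-negative counts.
#' @return Integer patient count.
#' @examples
#' estimate_patients(c(400, 500, 600))  # 500
#' estimate_patients(c(100, 101))       # 101
#' @export
estimate_patients <- function(estimates) {
  if (length(estimates) == 0 || !is.numeric(estimates) ||
      any(!is.finite(estimates)) || any(estimates < 0)) {
    abort("`estimates` must be a non-empty vector of non-negative counts.",
          class = "oncobudget_validation_error")
  }
  as.integer(round_half_up(mean(estimates)))
}

#' Annual national cost of one indication
#'
#' @param course A `course_cost` or numeric net course cost, US$.
#' @param n_patients Annual number of patients treated (>= 0).
#' @return Net course cost times patients, US$/year.
#' @examples
#' annual_indication_cost(5619, 100)  # 561900
#' @export
annual_indication_cost <- function(course, n_patients) {
  check_non_negative_scalar(n_patients, "n_patients")
  as_net_usd(course) * n_patients
}

#' Keep the most cost-effective option per indication
#'
#' Alternative options serving the same clinical indication (shared
#' `option_group`) compete: only the one with the lowest cost per life-year
#' survives into budget totals and the affordability curve.  Selection spans
#' the whole assessment set jointly, so a group may straddle threshold
#' categories.  Ties break alphabetically by drug name, then by
#' `indication_id`, making the selection invariant to input order.
#' Non-assessable rows (undefined cost per life-year) cannot rank and are
#' dropped.
#'
#' @param assessments Assessment tibble (see [assess_catalog()]).
#' @return The retained assessments, one row per `option_group`.
#' @export
select_best_option <- function(assessments) {
  assessments |>
    dplyr::filter(!is.na(.data$cost_per_ly_usd)) |>
    dplyr::arrange(.data$cost_per_ly_usd, .data$drug_name, .data$indication_id) |>
    dplyr::group_by(.data$option_group) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cost_per_ly_usd, .data$drug_name, .data$indication_id)
}

#' Annual budget per threshold category
#'
#' @param assessments Assessment tibble, normally already best-option
#'   selected.
#' @return A tibble with `category`, `n_indications` and `annual_cost_usd`.
#' @export
category_totals <- function(assessments) {
  assessments |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_indications = dplyr::n(),
      annual_cost_usd = sum(.data$annual_cost_usd),
      .groups = "drop"
    )
}

#' Total annual budget under a cost-effectiveness threshold
#'
#' Sums annual costs over every assessment whose category is at or below the
#' chosen boundary category -- the money needed to fund all treatments
#' meeting that threshold.  Widening the boundary can only add indications,
#' so the total is monotone in the threshold.
#'
#' @param assessments Best-option-selected assessment tibble.
#' @param boundary Boundary category (one of the scheme labels).
#' @param scheme A [threshold_scheme()] (supplies the category order).
#' @return Total annual cost, US$/year.
#' @export
total_under_threshold <- function(assessments,
                                  boundary = "cost_effective",
                                  scheme = threshold_scheme()) {
  boundary <- match.arg(boundary, scheme$labels)
  if (nrow(assessments) == 0) return(0)
  keep_levels <- scheme$labels[seq_len(match(boundary, scheme$labels))]
  assessments |>
    dplyr::filter(!is.na(.data$category),
                  .data$category %in% keep_levels) |>
    dplyr::pull(.data$annual_cost_usd) |>
    sum()
}

#' Cumulative affordability curve
#'
#' Orders the selected assessments by ascending cost per life-year as a GDP
#' fraction (ties by annual cost, then drug name) and accumulates annual
#' costs: the curve of total budget required as a function of the
#' willingness-to-pay per life-year.  The data behind the cumulative
#' procurement-cost figure.
#'
#' @param assessments Best-option-selected assessment tibble.
#' @return An object of class `budget_curve`: a list with `points` (tibble
#'   of `indication_id`, `drug_name`, `cost_per_ly_usd`, `gdp_fraction`,
#'   `annual_cost_usd`, `cumulative_annual_cost_usd`) and `selection`.
#' @export
cumulative_curve <- function(assessments) {
  pts <- assessments |>
    dplyr::filter(!is.na(.data$cost_per_ly_usd)) |>
    dplyr::arrange(.data$gdp_fraction, .data$annual_cost_usd,
                   .data$drug_name) |>
    dplyr::mutate(cumulative_annual_cost_usd = cumsum(.data$annual_cost_usd)) |>
    dplyr::select(dplyr::all_of(c(
      "indication_id", "drug_name", "cost_per_ly_usd", "gdp_fraction",
      "annual_cost_usd", "cumulative_annual_cost_usd"
    )))
  structure(list(points = pts, selection = assessments$indication_id),
            class = "budget_curve")
}

#' Write the affordability curve as TSV
#'
#' @param curve A `budget_curve`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_budget_curve <- function(curve, path) {
  readr::write_tsv(curve$points, path)
  invisible(path)
}

#' Plot the cumulative affordability curve
#'
#' Step plot of cumulative annual cost against cost per life-year as a GDP
#' fraction, with vertical guides at the threshold multipliers.
#'
#' @param curve A `budget_curve`.
#' @param ctx An [economic_context()] (for the threshold guides).
#' @return A ggplot object.
#' @export
plot_budget_curve <- function(curve, ctx = economic_context()) {
  pts <- curve$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$gdp_fraction,
                                    y = .data$cumulative_annual_cost_usd / 1e6)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = ctx$threshold_multipliers,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Cost per life-year gained (fraction of per-capita GDP)",
      y = "Cumulative annual cost (US$ millions)",
      title = "Cumulative procurement cost of novel cancer drugs"
    ) +
    ggplot2::theme_minimal()
}
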