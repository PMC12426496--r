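# Report assembly: one call from catalog to league tables, budget totals,
# affordability curve and run log.

#' Run a full budget-impact assessment and write the report bundle
#'
#' Reads (or accepts) a catalog, assesses every record, and writes to
#' `out_dir`: one league-table CSV per threshold category
#' (`league_<category>.csv`, all assessable options), `totals.json` with
#' per-category and cumulative-under-threshold budgets (raw US$ and millions
#' at 1 dp) computed on the best option per indication, `curve.tsv` with the
#' cumulative affordability curve, and `run_log.txt` recording conventional
#' exclusions, undefined cost-per-life-year cases and negative net costs.
#'
#' @param catalog A path passed to [read_catalog()], or a list of
#'   [indication_record()] objects.
#' @param ctx An [economic_context()] or a path to a context YAML/JSON file.
#' @param out_dir Output directory (created if needed).
#' @param profile A [patient_profile()].
#' @param multipliers Optional override of the context's threshold
#'   multipliers.
#' @param exclusion_threshold_usd Conventional-drug exclusion bound.
#' @return Invisibly, a list with `assessments`, `selected`, `totals`,
#'   `curve` and `log`.
#' @export
run_assessment <- function(catalog, ctx = economic_context(),
                           out_dir = ".", profile = patient_profile(),
                           multipliers = NULL,
                           exclusion_threshold_usd = 1000) {
  if (is.character(ctx)) ctx <- read_economic_context(ctx)
  if (!is.null(multipliers)) ctx$threshold_multipliers <- as.numeric(multipliers)
  records <- if (is.character(catalog)) read_catalog(catalog) else catalog
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- threshold_scheme(ctx)

  assessments <- assess_catalog(records, ctx, profile,
                                exclusion_threshold_usd)
  log_lines <- attr(assessments, "log") %||% character(0)

  if (nrow(assessments) == 0) {
    warn("Catalog is empty: writing empty reports.")
    log_lines <- c(log_lines, "WARNING: catalog is empty.")
  }

  usable <- dplyr::filter(assessments, !.data$excluded_conventional,
                          .data$assessable)
  selected <- select_best_option(usable)

  for (cat in scheme$labels) {
    subset <- dplyr::filter(usable, .data$category == cat)
    if (nrow(subset) > 0) {
      write_league_table(subset, file.path(out_dir,
                                           paste0("league_", cat, ".csv")))
    }
  }

  per_category <- category_totals(selected)
  cumulative <- lapply(scheme$labels, function(b) {
    tot <- total_under_threshold(selected, b, scheme)
    list(total_usd = tot, total_millions_usd = round_half_up(tot / 1e6, 1))
  })
  names(cumulative) <- scheme$labels
  totals <- list(
    reference_year = ctx$reference_year,
    gdp_per_capita_usd = ctx$gdp_per_capita_usd,
    threshold_boundaries_usd = as.list(scheme$boundaries),
    n_records = nrow(assessments),
    n_excluded_conventional = sum(assessments$excluded_conventional),
    n_not_assessable = sum(!assessments$assessable),
    n_selected = nrow(selected),
    per_category = per_category,
    cumulative_under_threshold = cumulative
  )
  jsonlite::write_json(totals, file.path(out_dir, "totals.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  curve <- cumulative_curve(selected)
  write_budget_curve(curve, file.path(out_dir, "curve.tsv"))

  writeLines(c(sprintf("oncobudget run: %d records, %d selected options.",
                       nrow(assessments), nrow(selected)),
               log_lines),
             file.path(out_dir, "run_log.txt"))

  invisible(list(assessments = assessments, selected = selected,
                 totals = totals, curve = curve, log = log_lines))
}

#' Generate a synthetic catalog file
#'
#' Writes a flat-CSV catalog drawn by [generate_catalog()]; byte-identical
#' for identical configurations.
#'
#' @param cfg A [generator_config()].
#' @param out_path Output CSV path.
#' @return `out_path`, invisibly.
#' @export
run_generate <- function(cfg = generator_config(), out_path) {
  if (cfg$n_indications == 0) {
    readr::write_csv(catalog_template(), out_path, na = "")
    return(invisible(out_path))
  }
  cfg$max_components <- 1L  # the flat CSV dialect holds one component per row
  cat_gen <- generate_catalog(cfg)
  write_catalog(cat_gen$records, out_path)
  invisible(out_path)
}
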