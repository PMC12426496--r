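#' Reference patient profile
#'
#' Drug courses are priced for a single reference patient rather than a
#' patient-level distribution; the default (a 50 kg adult with a body surface
#' area of 1.3 m\eqn{^2}) is the reference adult male used for national
#' procurement costing in the 2021 Sri Lanka reference case.
#'
#' @param weight_kg Body weight in kilograms (used by `per_kg` dose rules).
#' @param body_surface_area_m2 Body surface area in square metres (used by
#'   `per_m2` dose rules).
#' @return An object of class `patient_profile`.
#' @examples
#' patient_profile()
#' patient_profile(weight_kg = 70, body_surface_area_m2 = 1.8)
#' @export
patient_profile <- function(weight_kg = 50, body_surface_area_m2 = 1.3) {
  check_positive_scalar(weight_kg, "weight_kg")
  check_positive_scalar(body_surface_area_m2, "body_surface_area_m2")
  structure(
    list(weight_kg = weight_kg, body_surface_area_m2 = body_surface_area_m2),
    class = "patient_profile"
  )
}

#' Economic context for one country-year
#'
#' Bundles the macro-economic quantities every downstream computation needs:
#' per-capita GDP (the unit of the WHO cost-effectiveness thresholds), the
#' exchange rate used to convert local-currency procurement prices to USD,
#' the life expectancy used to extrapolate curative survival gains, and the
#' GDP multipliers defining the threshold bands.
#'
#' Defaults are the 2021 Sri Lanka reference case: per-capita GDP US$3,815,
#' 200 LKR per US$, 77-year life expectancy, and WHO multipliers 1 / 3 / 4.
#'
#' @param gdp_per_capita_usd Per-capita gross domestic product, US$/year.
#' @param exchange_rate_lkr_per_usd Local currency units per US$.
#' @param life_expectancy_years Average life expectancy at birth, years.
#' @param threshold_multipliers Strictly increasing positive GDP multiples
#'   defining the category boundaries (default `c(1, 3, 4)`).
#' @param reference_year Calendar year the prices and GDP refer to.
#' @return An object of class `economic_context`.
#' @examples
#' economic_context()
#' @export
economic_context <- function(gdp_per_capita_usd = 3815,
                             exchange_rate_lkr_per_usd = 200,
                             life_expectancy_years = 77,
                             threshold_multipliers = c(1, 3, 4),
                             reference_year = 2021) {
  check_positive_scalar(gdp_per_capita_usd, "gdp_per_capita_usd")
  check_positive_scalar(exchange_rate_lkr_per_usd, "exchange_rate_lkr_per_usd")
  check_positive_scalar(life_expectancy_years, "life_expectancy_years")
  if (!is.numeric(threshold_multipliers) || length(threshold_multipliers) < 1 ||
      any(!is.finite(threshold_multipliers)) || any(threshold_multipliers <= 0) ||
      is.unsorted(threshold_multipliers, strictly = TRUE)) {
    abort("`threshold_multipliers` must be strictly increasing positive numbers.",
          class = "oncobudget_validation_error")
  }
  check_positive_scalar(reference_year, "reference_year")
  structure(
    list(
      gdp_per_capita_usd = gdp_per_capita_usd,
      exchange_rate_lkr_per_usd = exchange_rate_lkr_per_usd,
      life_expectancy_years = life_expectancy_years,
      threshold_multipliers = as.numeric(threshold_multipliers),
      reference_year = reference_year
    ),
    class = "economic_context"
  )
}

DOSE_RULES <- c("flat_per_admin", "per_kg", "per_m2")
SETTINGS <- c("curative", "palliative")
OUTCOME_MEASURES <- c("OS", "PFS", "DFS", "DSS", "RMST")

#' Regimen dosing component
#'
#' One drug within a regimen, with enough dosing information to price a full
#' course: the per-administration dose rule (flat, per kg, or per m\eqn{^2}
#' of body surface area), the administration cadence within a cycle, and the
#' procurement unit price per mg.  Continuously-dosed oral agents are encoded
#' as one flat-dose administration per day (`cycle_days = 1`).
#'
#' @param drug_name Drug identifier.
#' @param dose_rule One of `"flat_per_admin"`, `"per_kg"`, `"per_m2"`.
#' @param dose_value_mg Dose in mg per the rule's unit (mg, mg/kg, or
#'   mg/m\eqn{^2}).
#' @param admins_per_cycle Administrations per cycle (>= 1).
#' @param cycle_days Cycle length in days (> 0).
#' @param unit_price Procurement price per mg, in `currency`.
#' @param currency `"LKR"` (converted at the context exchange rate) or
#'   `"USD"`.
#' @return An object of class `regimen_component`.
#' @examples
#' regimen_component("trastuzumab", "per_kg", 6, 1, 21, unit_price = 50)
#' @export
regimen_component <- function(drug_name, dose_rule, dose_value_mg,
                              admins_per_cycle = 1, cycle_days = 21,
                              unit_price, currency = "LKR") {
  if (!is.character(drug_name) || length(drug_name) != 1 || !nzchar(drug_name)) {
    abort("`drug_name` must be a non-empty string.",
          class = "oncobudget_validation_error")
  }
  dose_rule <- match.arg(dose_rule, DOSE_RULES)
  check_non_negative_scalar(dose_value_mg, "dose_value_mg")
  if (!is_scalar_number(admins_per_cycle) || admins_per_cycle < 1) {
    abort("`admins_per_cycle` must be >= 1.", class = "oncobudget_validation_error")
  }
  check_positive_scalar(cycle_days, "cycle_days")
  check_non_negative_scalar(unit_price, "unit_price")
  currency <- match.arg(currency, c("LKR", "USD"))
  structure(
    list(
      drug_name = drug_name, dose_rule = dose_rule,
      dose_value_mg = dose_value_mg, admins_per_cycle = admins_per_cycle,
      cycle_days = cycle_days, unit_price = unit_price, currency = currency
    ),
    class = "regimen_component"
  )
}

#' Treatment regimen
#'
#' A set of dosing components given in a curative or palliative setting.
#' Curative regimens are predetermined by protocol (`planned_cycles`);
#' palliative regimens run until progression, so their exposure is derived
#' from trial evidence at costing time.  A regimen is either *additive*
#' (given on top of the comparator, so the full gross cost is incremental)
#' or *substitutive* (the comparator arm's drug cost is subtracted).
#'
#' @param components List of [regimen_component()] objects (at least one).
#' @param setting `"curative"` or `"palliative"`.
#' @param planned_cycles Protocol-fixed number of cycles (curative only).
#' @param additive If `TRUE`, the comparator cost is not subtracted.
#' @param comparator Optional comparator [regimen()] priced over the same
#'   exposure; `NULL` means the comparator drug cost is zero.
#' @return An object of class `regimen`.
#' @export
regimen <- function(components, setting, planned_cycles = NULL,
                    additive = FALSE, comparator = NULL) {
  if (inherits(components, "regimen_component")) components <- list(components)
  if (!is.list(components) || length(components) == 0 ||
      !all(vapply(components, inherits, logical(1), "regimen_component"))) {
    abort("`components` must be a non-empty list of regimen_component objects.",
          class = "oncobudget_validation_error")
  }
  setting <- match.arg(setting, SETTINGS)
  if (!is.null(planned_cycles)) {
    check_positive_scalar(planned_cycles, "planned_cycles")
  }
  if (setting == "curative" && is.null(planned_cycles)) {
    abort("Curative regimens are protocol-fixed: `planned_cycles` is required.",
          class = "oncobudget_validation_error")
  }
  if (!is.logical(additive) || length(additive) != 1 || is.na(additive)) {
    abort("`additive` must be TRUE or FALSE.", class = "oncobudget_validation_error")
  }
  if (!is.null(comparator) && !inherits(comparator, "regimen")) {
    abort("`comparator` must be a regimen or NULL.",
          class = "oncobudget_validation_error")
  }
  structure(
    list(
      components = components, setting = setting,
      planned_cycles = planned_cycles, additive = additive,
      comparator = comparator
    ),
    class = "regimen"
  )
}

#' Pivotal-trial evidence for one indication
#'
#' Carries the survival outcome the pivotal randomised trial reports, the
#' data needed to cost palliative exposure (median treatment duration, or
#' median PFS as its stand-in since palliative treatment usually continues
#' until progression), and the follow-up and age-at-diagnosis inputs the
#' curative extrapolation needs.  Toxicity and ESMO magnitude-of-clinical-
#' benefit labels are carried as pass-through metadata only.
#'
#' @param outcome_measure One of `"OS"`, `"PFS"`, `"DFS"`, `"DSS"`, `"RMST"`.
#' @param gain_value Survival gain: months (palliative) or an absolute
#'   survival-proportion gain at end of follow-up in `[0, 1]` (curative).
#' @param gain_unit `"months"` or `"proportion"`.
#' @param follow_up_years Trial follow-up in years (curative).
#' @param crossover `TRUE` when substantial control-arm crossover dilutes the
#'   OS difference (PFS gain is then the usable measure).
#' @param median_tx_months Median treatment duration, months (palliative).
#' @param median_pfs_months Median progression-free survival, months.
#' @param age_dx_years Mean age at diagnosis, years (curative).
#' @param toxicity_grade3plus Proportion with grade >= 3 toxicity (metadata).
#' @param esmo_mcbs ESMO magnitude-of-clinical-benefit label (metadata).
#' @return An object of class `trial_evidence`.
#' @examples
#' trial_evidence("OS", 16.8, "months", median_tx_months = 14)
#' trial_evidence("DFS", 0.5, "proportion", follow_up_years = 3,
#'                age_dx_years = 64.5)
#' @export
trial_evidence <- function(outcome_measure, gain_value,
                           gain_unit = c("months", "proportion"),
                           follow_up_years = NULL, crossover = FALSE,
                           median_tx_months = NULL, median_pfs_months = NULL,
                           age_dx_years = NULL, toxicity_grade3plus = NULL,
                           esmo_mcbs = NULL) {
  outcome_measure <- match.arg(outcome_measure, OUTCOME_MEASURES)
  gain_unit <- match.arg(gain_unit)
  if (gain_unit == "months") {
    check_non_negative_scalar(gain_value, "gain_value")
  } else {
    if (!is_scalar_number(gain_value) || gain_value < 0 || gain_value > 1) {
      abort("Proportion gains must lie in [0, 1].",
            class = "oncobudget_validation_error")
    }
  }
  if (!is.null(follow_up_years)) check_positive_scalar(follow_up_years, "follow_up_years")
  if (!is.null(median_tx_months)) check_non_negative_scalar(median_tx_months, "median_tx_months")
  if (!is.null(median_pfs_months)) check_non_negative_scalar(median_pfs_months, "median_pfs_months")
  if (!is.null(age_dx_years)) check_positive_scalar(age_dx_years, "age_dx_years")
  structure(
    list(
      outcome_measure = outcome_measure, gain_value = gain_value,
      gain_unit = gain_unit, follow_up_years = follow_up_years,
      crossover = isTRUE(crossover), median_tx_months = median_tx_months,
      median_pfs_months = median_pfs_months, age_dx_years = age_dx_years,
      toxicity_grade3plus = toxicity_grade3plus, esmo_mcbs = esmo_mcbs
    ),
    class = "trial_evidence"
  )
}

#' Drug-indication catalog record
#'
#' One assessable option: a drug regimen (or an already-priced course cost in
#' USD, as when transcribing published league tables), its trial evidence,
#' and the expert panel's patient-number estimates.  `option_group` links
#' alternative options that serve the same clinical indication (for example
#' the 250 mg and 1,000 mg abiraterone schedules, or gefitinib versus
#' erlotinib); only the most cost-effective member of each group enters the
#' national budget totals.
#'
#' @param indication_id Unique identifier naming disease + line + setting.
#' @param drug_name Drug identifier.
#' @param evidence A [trial_evidence()] object.
#' @param patient_estimates Non-empty vector of non-negative annual patient
#'   counts, one per expert.
#' @param regimen A [regimen()] object, or `NULL` when `course_cost_usd` is
#'   supplied directly.
#' @param course_cost_usd Pre-computed net course cost in USD (used instead
#'   of regimen-based costing when dosing data is unavailable).
#' @param setting `"curative"` or `"palliative"`; defaults to the regimen's
#'   setting and is required for priced records.
#' @param option_group Identifier grouping alternative options for the same
#'   indication; defaults to `indication_id` (a singleton group).
#' @return An object of class `indication_record`.
#' @export
indication_record <- function(indication_id, drug_name, evidence,
                              patient_estimates, regimen = NULL,
                              course_cost_usd = NULL, setting = NULL,
                              option_group = indication_id) {
  for (nm in c("indication_id", "drug_name", "option_group")) {
    v <- get(nm)
    if (!is.character(v) || length(v) != 1 || !nzchar(v)) {
      abort(sprintf("`%s` must be a non-empty string.", nm),
            class = "oncobudget_validation_error")
    }
  }
  if (!inherits(evidence, "trial_evidence")) {
    abort("`evidence` must be a trial_evidence object.",
          class = "oncobudget_validation_error")
  }
  if (length(patient_estimates) == 0 || !is.numeric(patient_estimates) ||
      any(!is.finite(patient_estimates)) || any(patient_estimates < 0)) {
    abort("`patient_estimates` must be a non-empty vector of non-negative counts.",
          class = "oncobudget_validation_error")
  }
  if (is.null(regimen) && is.null(course_cost_usd)) {
    abort("Provide either a `regimen` or a pre-priced `course_cost_usd`.",
          class = "oncobudget_validation_error")
  }
  if (!is.null(regimen)) {
    if (!inherits(regimen, "regimen")) {
      abort("`regimen` must be a regimen object.",
            class = "oncobudget_validation_error")
    }
    setting <- setting %||% regimen$setting
  }
  if (!is.null(course_cost_usd)) check_non_negative_scalar(course_cost_usd, "course_cost_usd")
  setting <- match.arg(setting, SETTINGS)
  # Setting-dependent evidence invariants live here, where both are known.
  if (setting == "palliative" && evidence$gain_unit != "months") {
    abort(sprintf("[%s] palliative evidence must report its gain in months.", indication_id),
          class = "oncobudget_validation_error")
  }
  if (setting == "curative") {
    if (evidence$gain_unit != "proportion" || is.null(evidence$follow_up_years)) {
      abort(sprintf(
        "[%s] curative evidence needs a proportion gain and follow_up_years.",
        indication_id
      ), class = "oncobudget_validation_error")
    }
  }
  structure(
    list(
      indication_id = indication_id, option_group = option_group,
      drug_name = drug_name, setting = setting, regimen = regimen,
      evidence = evidence, patient_estimates = as.numeric(patient_estimates),
      course_cost_usd = course_cost_usd
    ),
    class = "indication_record"
  )
}

# Canonical flat-CSV catalog schema (one dosing component per row; a
# comparator is referenced by the indication_id of another row in the file).
CATALOG_COLUMNS <- c(
  "indication_id", "option_group", "drug_name", "setting", "dose_rule",
  "dose_value_mg", "admins_per_cycle", "cycle_days", "planned_cycles",
  "unit_price", "currency", "additive", "comparator_id", "outcome_measure",
  "gain_value", "gain_unit", "follow_up_years", "crossover",
  "median_tx_months", "median_pfs_months", "age_dx_years", "estimates"
)

catalog_col_types <- function() {
  readr::cols(
    indication_id = readr::col_character(),
    option_group = readr::col_character(),
    drug_name = readr::col_character(),
    setting = readr::col_character(),
    dose_rule = readr::col_character(),
    dose_value_mg = readr::col_double(),
    admins_per_cycle = readr::col_double(),
    cycle_days = readr::col_double(),
    planned_cycles = readr::col_double(),
    unit_price = readr::col_double(),
    currency = readr::col_character(),
    additive = readr::col_logical(),
    comparator_id = readr::col_character(),
    outcome_measure = readr::col_character(),
    gain_value = readr::col_double(),
    gain_unit = readr::col_character(),
    follow_up_years = readr::col_double(),
    crossover = readr::col_logical(),
    median_tx_months = readr::col_double(),
    median_pfs_months = readr::col_double(),
    age_dx_years = readr::col_double(),
    estimates = readr::col_character()
  )
}

na_null <- function(x) if (length(x) == 0 || is.na(x)) NULL else x

row_to_evidence <- function(row) {
  trial_evidence(
    outcome_measure = row$outcome_measure,
    gain_value = row$gain_value,
    gain_unit = row$gain_unit,
    follow_up_years = na_null(row$follow_up_years),
    crossover = isTRUE(row$crossover),
    median_tx_months = na_null(row$median_tx_months),
    median_pfs_months = na_null(row$median_pfs_months),
    age_dx_years = na_null(row$age_dx_years)
  )
}

row_to_regimen <- function(row, comparator = NULL) {
  comp <- regimen_component(
    drug_name = row$drug_name, dose_rule = row$dose_rule,
    dose_value_mg = row$dose_value_mg,
    admins_per_cycle = row$admins_per_cycle, cycle_days = row$cycle_days,
    unit_price = row$unit_price, currency = row$currency
  )
  regimen(
    components = list(comp), setting = row$setting,
    planned_cycles = na_null(row$planned_cycles),
    additive = isTRUE(row$additive), comparator = comparator
  )
}

parse_estimates <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Read a drug-indication catalog
#'
#' Two dialects are supported.  The flat CSV dialect has one dosing component
#' per row (columns documented in [catalog_template()]); `comparator_id`
#' references the `indication_id` of another row in the same file whose
#' regimen is priced as the comparator arm, and rows referenced only as
#' comparators may leave `estimates` empty (they are then not returned as
#' assessable records).  The nested JSON dialect mirrors the in-memory
#' structures and supports multi-component regimens with inline comparators.
#'
#' @param path Path to a `.csv` or `.json` catalog file.
#' @param schema `"auto"` (by file extension), `"csv"`, or `"json"`.
#' @return A list of [indication_record()] objects, in file order.
#' @export
read_catalog <- function(path, schema = c("auto", "csv", "json")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(sprintf("Catalog file not found: %s", path),
          class = "oncobudget_schema_error")
  }
  if (schema == "auto") {
    schema <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (schema == "json") read_catalog_json(path) else read_catalog_csv(path)
}

read_catalog_csv <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing_cols <- setdiff(CATALOG_COLUMNS, header)
  if (length(missing_cols) > 0) {
    abort(sprintf("Catalog is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "oncobudget_schema_error")
  }
  df <- readr::read_csv(path, col_types = catalog_col_types(),
                        progress = FALSE, na = c("", "NA"))
  if (nrow(df) == 0) return(list())
  rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  names(rows) <- df$indication_id
  comparator_ids <- unique(stats::na.omit(df$comparator_id))

  records <- list()
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    est <- parse_estimates(row$estimates)
    comparator_only <- length(est) == 0 && row$indication_id %in% comparator_ids
    if (comparator_only) next
    rec <- withCallingHandlers(
      {
        comparator <- NULL
        if (!is.na(row$comparator_id)) {
          cmp_row <- rows[[row$comparator_id]]
          if (is.null(cmp_row)) {
            abort(sprintf("comparator_id '%s' does not match any row.",
                          row$comparator_id),
                  class = "oncobudget_schema_error")
          }
          comparator <- row_to_regimen(cmp_row)
        }
        indication_record(
          indication_id = row$indication_id,
          option_group = if (is.na(row$option_group)) row$indication_id else row$option_group,
          drug_name = row$drug_name,
          regimen = row_to_regimen(row, comparator = comparator),
          evidence = row_to_evidence(row),
          patient_estimates = est
        )
      },
      error = function(e) {
        abort(sprintf("Catalog row %d (%s): %s", i, row$indication_id,
                      conditionMessage(e)),
              class = class(e)[1], parent = e)
      }
    )
    records[[length(records) + 1L]] <- rec
  }
  records
}

read_catalog_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    build_regimen <- function(rg) {
      if (is.null(rg)) return(NULL)
      comps <- lapply(rg$components, function(cp) {
        regimen_component(cp$drug_name, cp$dose_rule, cp$dose_value_mg,
                          cp$admins_per_cycle, cp$cycle_days, cp$unit_price,
                          cp$currency %||% "LKR")
      })
      regimen(comps, rg$setting, planned_cycles = rg$planned_cycles,
              additive = isTRUE(rg$additive),
              comparator = build_regimen(rg$comparator))
    }
    ev <- r$evidence
    indication_record(
      indication_id = r$indication_id,
      option_group = r$option_group %||% r$indication_id,
      drug_name = r$drug_name,
      regimen = build_regimen(r$regimen),
      course_cost_usd = r$course_cost_usd,
      setting = r$setting,
      evidence = trial_evidence(
        ev$outcome_measure, ev$gain_value, ev$gain_unit,
        follow_up_years = ev$follow_up_years, crossover = isTRUE(ev$crossover),
        median_tx_months = ev$median_tx_months,
        median_pfs_months = ev$median_pfs_months,
        age_dx_years = ev$age_dx_years
      ),
      patient_estimates = unlist(r$patient_estimates)
    )
  })
}

#' Write a catalog of single-component regimens to flat CSV
#'
#' The inverse of the CSV dialect of [read_catalog()].  Comparator regimens
#' are written as companion rows (suffix `_comparator`, empty estimates)
#' referenced through `comparator_id`.
#'
#' @param records List of [indication_record()] objects whose regimens have a
#'   single component (the flat dialect cannot express more).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(records, path) {
  rec_to_row <- function(id, option_group, drug_name, setting, comp,
                         planned_cycles, additive, comparator_id, ev, est) {
    tibble(
      indication_id = id, option_group = option_group, drug_name = drug_name,
      setting = setting, dose_rule = comp$dose_rule,
      dose_value_mg = comp$dose_value_mg,
      admins_per_cycle = comp$admins_per_cycle, cycle_days = comp$cycle_days,
      planned_cycles = planned_cycles %||% NA_real_,
      unit_price = comp$unit_price, currency = comp$currency,
      additive = additive, comparator_id = comparator_id %||% NA_character_,
      outcome_measure = ev$outcome_measure %||% NA_character_,
      gain_value = ev$gain_value %||% NA_real_,
      gain_unit = ev$gain_unit %||% NA_character_,
      follow_up_years = ev$follow_up_years %||% NA_real_,
      crossover = isTRUE(ev$crossover),
      median_tx_months = ev$median_tx_months %||% NA_real_,
      median_pfs_months = ev$median_pfs_months %||% NA_real_,
      age_dx_years = ev$age_dx_years %||% NA_real_,
      estimates = if (length(est) > 0) paste(est, collapse = ";") else NA_character_
    )
  }
  out <- list()
  for (rec in records) {
    if (is.null(rec$regimen) || length(rec$regimen$components) != 1) {
      abort(sprintf("[%s] flat CSV requires a single-component regimen.",
                    rec$indication_id),
            class = "oncobudget_schema_error")
    }
    comparator_id <- NULL
    cmp <- rec$regimen$comparator
    if (!is.null(cmp)) {
      if (length(cmp$components) != 1) {
        abort(sprintf("[%s] flat CSV requires a single-component comparator.",
                      rec$indication_id),
              class = "oncobudget_schema_error")
      }
      comparator_id <- paste0(rec$indication_id, "_comparator")
      out[[length(out) + 1L]] <- rec_to_row(
        comparator_id, comparator_id, cmp$components[[1]]$drug_name,
        cmp$setting, cmp$components[[1]], cmp$planned_cycles, FALSE, NULL,
        list(outcome_measure = "OS", gain_value = 0, gain_unit = "months"),
        numeric(0)
      )
    }
    out[[length(out) + 1L]] <- rec_to_row(
      rec$indication_id, rec$option_group, rec$drug_name, rec$setting,
      rec$regimen$components[[1]], rec$regimen$planned_cycles,
      rec$regimen$additive, comparator_id, rec$evidence, rec$patient_estimates
    )
  }
  readr::write_csv(dplyr::bind_rows(out), path, na = "")
  invisible(path)
}

#' Header-only catalog template
#'
#' @return A zero-row tibble with the flat CSV catalog columns.
#' @export
catalog_template <- function() {
  tpl <- as_tibble(stats::setNames(
    rep(list(character(0)), length(CATALOG_COLUMNS)), CATALOG_COLUMNS
  ))
  tpl
}

LEAGUE_COLUMNS <- c(
  "category", "indication_id", "option_group", "drug_name", "setting",
  "gain_value", "gain_unit", "course_cost_usd", "cost_per_ly_usd",
  "gdp_fraction", "n_patients", "annual_cost_usd"
)

#' Write an ICER league table
#'
#' Writes assessments in the conventional league-table layout: drug, setting,
#' survival gain, course cost, cost per life-year, GDP fraction, patient
#' numbers and annual cost, sorted by ascending GDP fraction within category
#' (ties broken alphabetically by drug name).  Costs are reported at 2
#' decimal places, cost per life-year rounded half-up to whole US$ and GDP
#' fractions to 2 decimal places; internal arithmetic is never rounded.
#'
#' @param assessments Assessment tibble (see [assess_catalog()]), non-empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_league_table <- function(assessments, path) {
  if (is.null(assessments) || nrow(assessments) == 0) {
    abort("`assessments` must be non-empty.", class = "oncobudget_validation_error")
  }
  out <- assessments |>
    dplyr::arrange(.data$category, .data$gdp_fraction, .data$drug_name) |>
    dplyr::mutate(
      course_cost_usd = round_half_up(.data$course_cost_usd, 2),
      cost_per_ly_usd = round_half_up(.data$cost_per_ly_usd, 0),
      gdp_fraction = round_half_up(.data$gdp_fraction, 2),
      annual_cost_usd = round_half_up(.data$annual_cost_usd, 2)
    ) |>
    dplyr::select(dplyr::all_of(LEAGUE_COLUMNS))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read back a league table written by [write_league_table()]
#'
#' @param path CSV path.
#' @return A tibble with the league-table columns.
#' @export
read_league_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read an economic-context configuration file
#'
#' Accepts YAML or JSON with keys `gdp_per_capita_usd`, `exchange_rate`
#' (or `exchange_rate_lkr_per_usd`), `life_expectancy_years`, `multipliers`
#' (or `threshold_multipliers`) and optionally `reference_year`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return An [economic_context()] object.
#' @export
read_economic_context <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Context file not found: %s", path),
          class = "oncobudget_schema_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  economic_context(
    gdp_per_capita_usd = cfg$gdp_per_capita_usd,
    exchange_rate_lkr_per_usd = cfg$exchange_rate_lkr_per_usd %||% cfg$exchange_rate,
    life_expectancy_years = cfg$life_expectancy_years,
    threshold_multipliers = unlist(cfg$threshold_multipliers %||% cfg$multipliers %||% c(1, 3, 4)),
    reference_year = cfg$reference_year %||% 2021
  )
}
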