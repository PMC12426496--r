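# Synthetic catalog generator with a known ground truth.  The oracle is a
# deliberately naive, self-contained loop that re-derives every quantity
# from the raw record parameters without touching the pipeline's code path.

#' Configuration for the synthetic catalog generator
#'
#' Defaults emulate the structure of a national novel-oncology-drug catalog:
#' about one indication in eight is adjuvant/curative, survival gains span a
#' few months to three years, three experts estimate patient numbers with
#' roughly 20% dispersion, and a handful of indications have a competing
#' alternative option.
#'
#' @param seed Integer RNG seed; the same seed reproduces the same catalog.
#' @param n_indications Number of assessable records.
#' @param n_option_groups_with_alternatives Number of option groups holding
#'   two competing options (consumes the first `2 *` this many records).
#' @param price_range_lkr_per_mg Unit-price interval, LKR per mg.
#' @param gain_range_months Palliative survival-gain interval, months.
#' @param curative_fraction Proportion of option groups in the curative
#'   setting.
#' @param expert_count Experts estimating patient numbers (default 3).
#' @param estimate_noise Log-normal sigma of expert dispersion.
#' @param max_components Maximum dosing components per regimen (the flat CSV
#'   dialect needs 1; the default in-memory catalogs allow 2).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_indications = 50,
                             n_option_groups_with_alternatives =
                               min(5, n_indications %/% 2),
                             price_range_lkr_per_mg = c(1, 400),
                             gain_range_months = c(2, 36),
                             curative_fraction = 0.12,
                             expert_count = 3, estimate_noise = 0.2,
                             max_components = 2) {
  check_non_negative_scalar(n_indications, "n_indications")
  check_non_negative_scalar(n_option_groups_with_alternatives,
                            "n_option_groups_with_alternatives")
  if (2 * n_option_groups_with_alternatives > n_indications) {
    abort("Too many alternative-option groups for the catalog size.",
          class = "oncobudget_validation_error")
  }
  for (rng in list(price_range_lkr_per_mg, gain_range_months)) {
    if (length(rng) != 2 || rng[1] >= rng[2] || any(rng <= 0)) {
      abort("Ranges must be non-degenerate positive intervals.",
            class = "oncobudget_validation_error")
    }
  }
  if (curative_fraction < 0 || curative_fraction > 1) {
    abort("`curative_fraction` must lie in [0, 1].",
          class = "oncobudget_validation_error")
  }
  check_positive_scalar(expert_count, "expert_count")
  check_non_negative_scalar(estimate_noise, "estimate_noise")
  structure(
    list(
      seed = as.integer(seed), n_indications = as.integer(n_indications),
      n_option_groups_with_alternatives = as.integer(n_option_groups_with_alternatives),
      price_range_lkr_per_mg = as.numeric(price_range_lkr_per_mg),
      gain_range_months = as.numeric(gain_range_months),
      curative_fraction = curative_fraction,
      expert_count = as.integer(expert_count),
      estimate_noise = estimate_noise,
      max_components = as.integer(max_components)
    ),
    class = "generator_config"
  )
}

random_component <- function(drug_name, cfg) {
  rule <- sample(DOSE_RULES, 1)
  dose <- switch(rule,
    flat_per_admin = runif(1, 100, 1500),
    per_kg = runif(1, 1, 20),
    per_m2 = runif(1, 20, 300)
  )
  regimen_component(
    drug_name = drug_name, dose_rule = rule, dose_value_mg = dose,
    admins_per_cycle = sample(1:4, 1),
    cycle_days = sample(c(7, 14, 21, 28), 1),
    unit_price = runif(1, cfg$price_range_lkr_per_mg[1],
                       cfg$price_range_lkr_per_mg[2]),
    currency = "LKR"
  )
}

random_record <- function(i, option_group, setting, cfg) {
  id <- sprintf("ind_%03d", i)
  drug <- sprintf("drug_%03d", i)
  n_comp <- sample(seq_len(cfg$max_components), 1)
  components <- lapply(seq_len(n_comp), function(j) {
    random_component(if (j == 1) drug else paste0(drug, "_partner"), cfg)
  })
  additive <- runif(1) < 0.3
  comparator <- NULL
  if (!additive && runif(1) < 0.8) {
    cheap_cfg <- cfg
    cheap_cfg$price_range_lkr_per_mg <- cfg$price_range_lkr_per_mg / 5
    comparator <- regimen(
      list(random_component(paste0(drug, "_comparator"), cheap_cfg)),
      setting = setting,
      planned_cycles = if (setting == "curative") sample(4:8, 1) else NULL
    )
  }
  reg <- regimen(
    components, setting = setting,
    planned_cycles = if (setting == "curative") sample(4:8, 1) else NULL,
    additive = additive, comparator = comparator
  )
  evidence <- if (setting == "curative") {
    trial_evidence(
      outcome_measure = if (runif(1) < 0.4) "OS" else "DFS",
      gain_value = runif(1, 0.02, 0.3), gain_unit = "proportion",
      follow_up_years = sample(c(3, 5, 10), 1),
      age_dx_years = runif(1, 40, 65)
    )
  } else {
    measure <- sample(c("OS", "PFS", "RMST"), 1, prob = c(0.7, 0.2, 0.1))
    gain <- runif(1, cfg$gain_range_months[1], cfg$gain_range_months[2])
    trial_evidence(
      outcome_measure = measure, gain_value = gain, gain_unit = "months",
      crossover = measure == "PFS",
      median_tx_months = if (runif(1) < 0.6) runif(1, 1, gain + 6) else NULL,
      median_pfs_months = runif(1, 1, gain + 3)
    )
  }
  base_n <- sample(20:800, 1)
  estimates <- pmax(0, round(base_n * rlnorm(cfg$expert_count, 0,
                                             cfg$estimate_noise)))
  indication_record(
    indication_id = id, option_group = option_group, drug_name = drug,
    regimen = reg, evidence = evidence, patient_estimates = estimates
  )
}

#' Generate a synthetic catalog with known ground truth
#'
#' Draws a reproducible catalog of dosing regimens, trial evidence and
#' expert patient estimates, together with a `GroundTruth` tibble computed
#' by an independent naive recomputation (see [ground_truth()]) of every
#' course cost, life-year gain, cost per life-year, category and annual
#' cost.  Calling this sets the RNG seed from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @param ctx An [economic_context()].
#' @param profile A [patient_profile()].
#' @return A list with `records` (list of [indication_record()]) and
#'   `truth` (tibble).
#' @export
generate_catalog <- function(cfg = generator_config(),
                             ctx = economic_context(),
                             profile = patient_profile()) {
  set.seed(cfg$seed)
  n <- cfg$n_indications
  records <- vector("list", n)
  n_alt <- cfg$n_option_groups_with_alternatives
  group_of <- function(i) {
    if (i <= 2 * n_alt) sprintf("grp_%02d", ceiling(i / 2))
    else sprintf("ind_%03d", i)
  }
  # Setting is drawn per option group so competing options share it.
  group_setting <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    g <- group_of(i)
    if (is.null(group_setting[[g]])) {
      group_setting[[g]] <- if (runif(1) < cfg$curative_fraction) "curative"
                            else "palliative"
    }
    records[[i]] <- random_record(i, g, group_setting[[g]], cfg)
  }
  list(records = records, truth = ground_truth(records, ctx, profile))
}

#' Naive ground-truth recomputation (the oracle)
#'
#' Recomputes every assessed quantity from the raw record parameters in one
#' plain loop, sharing no code with the pipeline: dose arithmetic, currency
#' conversion, the ceiling cycle rule, comparator subtraction, life-year
#' conversion, threshold classification, patient means and annual costs are
#' all re-derived inline.  Used to verify [assess_catalog()] on generated
#' catalogs.
#'
#' @param records List of [indication_record()] objects with full regimens.
#' @param ctx An [economic_context()].
#' @param profile A [patient_profile()].
#' @return A tibble with one row per record.
#' @export
ground_truth <- function(records, ctx = economic_context(),
                         profile = patient_profile()) {
  gdp <- ctx$gdp_per_capita_usd
  fx <- ctx$exchange_rate_lkr_per_usd
  le <- ctx$life_expectancy_years
  bounds <- ctx$threshold_multipliers * gdp
  labels <- c("highly_cost_effective", "cost_effective",
              "potentially_cost_effective", "not_cost_effective")
  out <- list()
  for (rec in records) {
    reg <- rec$regimen
    ev <- rec$evidence
    months <- NA_real_
    if (reg$setting == "palliative") {
      months <- if (!is.null(ev$median_tx_months)) ev$median_tx_months
                else ev$median_pfs_months
    }
    price_arm <- function(arm, cycles_fallback) {
      total <- 0
      for (cp in arm$components) {
        dose <- if (cp$dose_rule == "flat_per_admin") cp$dose_value_mg
                else if (cp$dose_rule == "per_kg") cp$dose_value_mg * profile$weight_kg
                else cp$dose_value_mg * profile$body_surface_area_m2
        price <- if (cp$currency == "USD") cp$unit_price else cp$unit_price / fx
        n_adm <- if (arm$setting == "curative") {
          cycles <- if (is.null(arm$planned_cycles)) cycles_fallback
                    else arm$planned_cycles
          cycles * cp$admins_per_cycle
        } else {
          ceiling(months * 30.44 / cp$cycle_days) * cp$admins_per_cycle
        }
        total <- total + dose * price * n_adm
      }
      total
    }
    gross <- price_arm(reg, reg$planned_cycles)
    comparator <- if (!reg$additive && !is.null(reg$comparator)) {
      price_arm(reg$comparator, reg$planned_cycles)
    } else 0
    net <- if (reg$additive) gross else gross - comparator
    ly <- if (reg$setting == "palliative") {
      ev$gain_value / 12
    } else {
      ev$gain_value * max(0, le - ev$age_dx_years - ev$follow_up_years)
    }
    clyg <- if (ly > 0) net / ly else NA_real_
    category <- if (is.na(clyg)) NA_character_
      else if (clyg < bounds[1]) labels[1]
      else if (clyg <= bounds[2]) labels[2]
      else if (clyg <= bounds[3]) labels[3]
      else labels[4]
    m <- mean(rec$patient_estimates)
    n_pat <- floor(m + 0.5)
    out[[length(out) + 1L]] <- tibble(
      indication_id = rec$indication_id,
      option_group = rec$option_group,
      gross_cost_usd = gross,
      comparator_cost_usd = comparator,
      course_cost_usd = net,
      excluded_conventional = net < 1000,
      ly_gained = ly,
      cost_per_ly_usd = clyg,
      gdp_fraction = clyg / gdp,
      category = category,
      n_patients = as.integer(n_pat),
      annual_cost_usd = net * n_pat
    )
  }
  dplyr::bind_rows(out)
}

#' Scale every unit price in a catalog
#'
#' Multiplies the unit price of every component -- novel and comparator --
#' by `k`.  Course costs, and hence every budget total, are homogeneous of
#' degree one in prices, which makes this useful for sensitivity checks and
#' invariance tests.
#'
#' @param records List of [indication_record()] objects with regimens.
#' @param k Positive scale factor.
#' @return The records with scaled prices.
#' @export
scale_unit_prices <- function(records, k) {
  check_positive_scalar(k, "k")
  scale_reg <- function(reg) {
    if (is.null(reg)) return(NULL)
    reg$components <- lapply(reg$components, function(cp) {
      cp$unit_price <- cp$unit_price * k
      cp
    })
    reg$comparator <- scale_reg(reg$comparator)
    reg
  }
  lapply(records, function(rec) {
    rec$regimen <- scale_reg(rec$regimen)
    rec
  })
}
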