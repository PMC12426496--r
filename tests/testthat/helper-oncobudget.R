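# Small builders used across test files.  All fixtures are built in code.

flat_component <- function(price_usd_per_mg = 1, dose_mg = 100,
                           admins = 1, cycle_days = 21,
                           drug = "synthetic_drug") {
  regimen_component(drug, "flat_per_admin", dose_mg,
                    admins_per_cycle = admins, cycle_days = cycle_days,
                    unit_price = price_usd_per_mg, currency = "USD")
}

palliative_evidence <- function(gain_months = 12, tx_months = gain_months,
                                measure = "OS") {
  trial_evidence(measure, gain_months, "months",
                 median_tx_months = tx_months)
}

curative_evidence <- function(delta = 0.1, follow_up = 10, age = 47) {
  trial_evidence("DFS", delta, "proportion", follow_up_years = follow_up,
                 age_dx_years = age)
}

palliative_record <- function(id = "ind_pal", gain = 12, cost_usd_per_mg = 1,
                              estimates = c(100, 100, 100),
                              group = id, drug = "synthetic_drug") {
  indication_record(
    indication_id = id, option_group = group, drug_name = drug,
    regimen = regimen(list(flat_component(cost_usd_per_mg, drug = drug)),
                      "palliative"),
    evidence = palliative_evidence(gain),
    patient_estimates = estimates
  )
}
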