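# oncobudget

Budget-impact and cost-effectiveness screening of novel cancer drugs for
resource-limited health systems.

## The problem

A publicly funded health system with a fixed drug budget cannot buy every
novel oncology agent at list price. `oncobudget` implements the rapid
league-table screen used for national formulary prioritisation: price a
full treatment course from procurement unit prices, convert pivotal-trial
survival gains into life-years, rank indications by cost per life-year
gained, classify them against WHO per-capita-GDP multiples, and accumulate
per-indication annual budgets into an affordability curve. It is aimed at
formulary committees, procurement analysts and health-economics researchers
working where QALY data and Markov modelling are out of reach.

## The model

For each drug–indication pair *i*:

- **Course cost** `C_i` (US$): Σ over regimen components of
  dose × unit price × administrations, for a 50 kg / 1.3 m² reference
  adult. Curative courses use the protocol's planned cycles; palliative
  courses run over the trial's median treatment duration (or median PFS),
  with `ceiling(months × 30.44 / cycle_days)` cycles. Substitutive
  regimens subtract the comparator arm's drug cost over the same exposure.
- **Life-years gained** `E_i`: palliative, median OS gain (RMST preferred,
  PFS under crossover) in months ÷ 12; curative,
  `Δsurvival × max(0, LE − age at diagnosis − follow-up)` —
  survivors at end of follow-up are assumed to live to life expectancy.
- **Cost per life-year** `CLYG_i = C_i / E_i`, classified against
  1× / 3× / 4× per-capita GDP (2021 Sri Lanka reference case:
  3,815 / 11,445 / 15,260 US$/LY) as highly cost-effective /
  cost-effective / potentially cost-effective with price reduction /
  not cost-effective.
- **Annual budget** `B_i = C_i × n_i`, with `n_i` the half-up-rounded mean
  of independent expert patient estimates; only the cheapest-per-life-year
  option per indication enters national totals and the cumulative curve.

De-escalated schedules proven non-inferior (250 mg abiraterone with food,
6-month adjuvant trastuzumab) are costed at their own price but credited
with the standard schedule's life-years.

## Worked example

The package ships a verbatim transcription of the two published
league-table tiers of the 2021 Sri Lanka reference case:

```r
library(oncobudget)

fx <- tables_fixture()                      # 31 rows, self-audited
assessments <- fixture_assessments(fx)      # published record
selected <- select_best_option(assessments) # cheapest option per indication

sum(selected$annual_cost_usd[selected$category == "cost_effective"])
#> [1] 7209904

total_under_threshold(selected, "cost_effective") / 1e6
#> [1] 13.00793

head(cumulative_curve(selected)$points, 3)
#> # A tibble: 3 × 6
#>   indication_id            drug_name  cost_per_ly_usd gdp_fraction annual_cost_usd cumulative_annual_cost_usd
#>   <chr>                    <chr>                <dbl>        <dbl>           <dbl>                      <dbl>
#> 1 rituximab_follicular_ma… rituximab              795         0.06           76748                      76748
#> 2 bortezomib_mm_first_line bortezomib             437         0.11          230216                     306964
#> 3 rituximab_nhl_first_line rituximab              530         0.14          775235                    1082199
```

The first number is the annual budget of the cost-effective tier after
keeping only the most cost-effective option per indication (two options are
displaced by cheaper cross-tier alternatives); the second is the cumulative
budget, in millions, needed to fund everything up to 3× GDP per life-year;
the curve rows show the running total as the willingness-to-pay grows.

For your own data: `read_catalog()` loads a dosing-level CSV/JSON catalog
(schema in `?read_catalog` and `catalog_template()`), `assess_catalog()`
produces the full assessment tibble, and `run_assessment()` writes league
tables, budget totals, the curve TSV and a run log in one call.
`generate_catalog()` draws synthetic catalogs with a known ground truth for
testing. A thin CLI over these functions lives at `inst/cli/oncobudget.R`
(subcommands `assess`, `generate`, `fixture`, `curve`).

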