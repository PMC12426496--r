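---
title: "Budget-impact screening of novel cancer drugs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Budget-impact screening of novel cancer drugs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncobudget)
library(dplyr)
```

## The problem

Publicly funded health systems in lower-middle-income countries buy
oncology drugs out of a fixed procurement budget. Without an explicit
willingness-to-pay rule, expensive novel agents are bought until the budget
runs out, after which *every* drug is in shortage. `oncobudget` implements a
deliberately simple screening pipeline that ranks each drug--indication pair
by its **cost per life-year gained** (CLYG), classifies it against
WHO-style per-capita-GDP multiples, and aggregates the per-indication
annual budgets into a cumulative affordability curve: how much money funds
everything up to a given willingness-to-pay.

This is a league-table screen, not a full health-economic evaluation: no
quality-of-life adjustment (no QALYs), no discounting, no Markov or
partitioned-survival modelling, and only direct drug-acquisition costs.
Those are deliberate scope limits, matching what is computable from public
procurement prices and published pivotal trials in settings without local
quality-of-life or stage-distribution data.

## The model

For each indication $i$ the pipeline computes

$$\mathrm{CLYG}_i = \frac{C_i}{E_i}, \qquad
  f_i = \frac{\mathrm{CLYG}_i}{\mathrm{GDP}_{pc}}, \qquad
  B_i = C_i \times n_i,$$

where $C_i$ is the net course cost per patient (US\$), $E_i$ the life-years
gained per patient, $f_i$ the GDP fraction used for threshold
classification, $n_i$ the expected annual number of patients, and $B_i$ the
annual national budget for the indication.

### Course cost $C_i$

A course is priced for a single reference patient — a 50 kg adult with
1.3 m² body surface area — because national procurement costing needs one
representative figure, not a patient-level distribution. Per administration,
a component doses `dose_value` mg (flat), `dose_value × weight` (per kg) or
`dose_value × BSA` (per m²); the cost is dose × unit price (LKR prices are
converted at the context exchange rate, 200 LKR/US\$ in the 2021 reference
case).

* **Curative** regimens are protocol-fixed: administrations =
  `planned_cycles × admins_per_cycle`.
* **Palliative** regimens run until progression. Exposure is the trial's
  median treatment duration, or median PFS when duration is unreported.
  Exposure maps to cycles as `ceiling(months × 30.44 / cycle_days)`:
  a started cycle is dispensed in full. (The ceiling is this package's
  convention; the floor alternative changes costs by at most one cycle.)
* **Substitutive** regimens subtract the comparator arm's drug cost, priced
  over the *same* exposure at the comparator's own cadence (own
  `planned_cycles` when curative and stated, else mirroring the novel
  regimen's). **Additive** regimens keep the full gross cost.
* Vial rounding and wastage are not modelled (continuous dose × unit price);
  nor are administration consumables, staffing or investigations.

Conventional cheap agents are screened out by the `< US$1,000` per-course
rule, applied **strictly** (a course at exactly 1,000 stays in).
`assess_catalog()` only *flags* such rows (`excluded_conventional`) because
the screen properly belongs at drug level, upstream of per-indication
incremental costing: several genuinely novel options (short-exposure or
de-escalated schedules) have net per-indication costs below 1,000 and must
not be silently dropped. `run_assessment()` drops flagged rows by default
for raw catalogs.

### Life-years gained $E_i$

* **Palliative**: the gain in median OS (months) divided by 12. RMST gains
  are preferred when reported (more robust under long-tailed immunotherapy
  curves); PFS gains substitute when control-arm crossover dilutes OS or OS
  is unavailable. The basis used is recorded per row for audit.
* **Curative**: the absolute survival-proportion gain $\Delta$ at end of
  trial follow-up, times the **residual life expectancy**
  $R = \max(0,\; LE - \text{age at diagnosis} - \text{follow-up})$ —
  survivors at end of follow-up are assumed to live to the population life
  expectancy (77 years in the reference case). The rule is implemented
  behind `residual_life_years()` so an alternative extrapolation can be
  swapped in. No discounting anywhere, consistent with the undiscounted
  league-table style of the screen.

De-escalated schedules proven non-inferior (a 250 mg-with-food abiraterone
schedule; 6-month adjuvant trastuzumab) are assumed to deliver the standard
schedule's gain: their cost is divided by the *standard* life-years
(`assess_deescalation()`), and both options stay in the same `option_group`.

### Thresholds and aggregation

With multipliers $(1, 3, 4)$ and $\mathrm{GDP}_{pc} = 3{,}815$ US\$, the
boundaries are 3,815 / 11,445 / 15,260 US\$ per life-year. Boundary
conventions: the 1× bound is *exclusive* for the highly-cost-effective band
("less than per-capita GDP"); the 3× and 4× bounds are *inclusive* for
their lower band ("between 1 and 3 times"). No published row sits on a
boundary, so the convention is documented rather than empirically forced.

Patient numbers are the arithmetic mean of the independent expert
estimates, rounded **half-up** to a whole patient (base R's half-even
rounding would turn 100.5 into 100). Reported figures use half-up rounding
throughout — whole US\$ for CLYG, 2 dp for GDP fractions and costs — while
internal arithmetic is never rounded.

Only the cheapest-per-life-year option of each `option_group` enters
national totals and the affordability curve, selected jointly across
threshold tiers (ties: drug name, then indication id, making selection
order-invariant). The curve sorts by GDP fraction (for computed rows this
equals sorting by CLYG) and accumulates annual costs.

## The shipped reference fixture

`tables_fixture()` loads a verbatim transcription of the two published
league-table tiers of the 2021 Sri Lanka reference case (17
highly-cost-effective + 14 cost-effective rows): printed course costs,
survival gains, CLYG, GDP fractions, patient counts, annual costs, and the
two footer totals (6,004,878.24 and 7,209,904 US\$).

Three caveats a user must know:

* **Self-audit.** At load time each row's CLYG is recomputed from its
  printed course cost and gain; rows disagreeing by more than 1 % relative
  are flagged `inconsistent = TRUE` (11 of 31 rows, including an obvious
  currency/typo artefact in the GIST course cost). Flags are computed,
  never hard-coded, and flagged rows are kept verbatim, never corrected.
  Re-assessing the fixture therefore moves some flagged rows across tiers;
  the published 17/14 tiering holds for the published record
  (`fixture_assessments(use = "published")`), not for recomputation.
* **Tolerance for unflagged rows.** Printed course costs are rounded to
  whole US\$, so recomputed CLYG can legitimately differ from the printed
  value by up to `1 + 0.5 / life-years` US\$; the test suite uses exactly
  that bound, and exact equality for the three rows whose printed inputs
  are exactly consistent.
* **Implied curative inputs.** The four curative rows need an age at
  diagnosis that the published tables do not print; the fixture carries the
  values implied by back-solving the published arithmetic (47, 64.5, 42.5
  and 62 years, with life expectancy 77), giving residual multipliers of
  20, 9.5, 31.5 and 5 years. These are synthetic reconstructions, labelled
  as such, not registry data.
* **First-tier footer.** The published first-tier total (6,004,878.24)
  retains the dearer of the two first-line EGFR options; strict
  minimum-CLYG selection keeps the cheaper one and yields 5,798,023. Both
  are reported; at million-level rounding both give the same headline
  (6 M, and 13.2 M jointly with the second tier).

## The synthetic generator and its oracle

`generate_catalog()` draws catalogs with the structure of a national
novel-drug formulary: default 50 indications of which ~12 % curative
(mirroring the roughly 10-in-90 adjuvant share of such formularies), 5
indication groups with two competing options, 1–2 dosing components per
regimen with unit prices of 1–400 LKR/mg, palliative gains of 2–36 months,
and three experts whose patient estimates scatter log-normally with
σ = 0.2 around a base count — a realistic ~20 % coefficient of variation
for recall-based estimates. These defaults were fixed once, up front, as
the package's study conditions.

Each generated catalog ships with a `GroundTruth` tibble computed by
`ground_truth()`: a deliberately naive single loop that re-derives every
dose, conversion, ceiling, subtraction, life-year, category, mean and
product inline, sharing no code with the pipeline. The acceptance check
requires pipeline–oracle agreement to 1e-9 relative on 20 catalogs × 50
indications (a scale chosen to exercise every branch while completing in
seconds on one core).

What the generator does **not** emulate: individual-patient survival
curves, real price correlation between drug classes, vial sizes, multi-line
treatment sequences, or real expert behaviour. Passing the oracle check
shows the pipeline's arithmetic is internally correct under the stated
conventions — not that those conventions match any particular health
system's contracts.

## Degenerate inputs and numerical choices

* Zero or negative life-year gains make CLYG undefined: reported as *not
  assessable* (classed condition, `NA` in the tibble), never ±Inf, and
  excluded from ranking and totals with a log entry.
* Negative net costs (comparator dearer than the novel agent) are kept but
  flagged in the run log.
* `estimate_patients()` rejects empty estimate vectors; zero estimates are
  allowed (an indication can be expected to treat no one in a given year).
* All currency arithmetic is double precision with rounding only at report
  time; printed-value comparisons in tests use the rounding-aware bounds
  above.

## Worked example

```{r example}
fx <- tables_fixture()
assessments <- fixture_assessments(fx, use = "published")
selected <- select_best_option(assessments)

sum(selected$annual_cost_usd[selected$category == "cost_effective"])
total_under_threshold(selected, "cost_effective") / 1e6

curve <- cumulative_curve(selected)
head(curve$points, 3)
```

```{r plot, fig.width = 6, fig.height = 4}
plot_budget_curve(curve)
```

## Known limitations

Life-years are not quality-adjusted, so the screen overstates benefit
relative to QALY-based thresholds; trial efficacy overstates real-world
effectiveness; median-based gains understate long-tail benefit where RMST
is unreported; the single reference patient ignores dose variation; and the
expert-mean patient counts carry unquantified uncertainty. The package
reports what the inputs imply — it does not fix the inputs.
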