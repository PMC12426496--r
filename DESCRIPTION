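Package: oncobudget
Title: Budget Impact and Cost-Effectiveness Screening of Novel Cancer
    Drugs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening novel oncology drugs in resource-limited
    health systems: prices a full treatment course from regimen dosing
    rules and a reference patient, converts pivotal-trial survival gains
    into life-years gained (including extrapolation to life expectancy in
    the curative setting), computes cost per life-year gained and
    classifies it against WHO GDP-per-capita multiple thresholds, and
    aggregates per-indication annual budgets into league tables,
    threshold-capped national totals and a cumulative affordability
    curve.  Ships a transcribed league-table fixture for the 2021 Sri
    Lanka reference case and a synthetic catalog generator with an
    independent ground-truth oracle for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
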