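Package: edexcess
Title: Excess Mortality from Emergency-Department Avoidance via
    Instrumental-Variable Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates excess non-COVID 28-day mortality caused by reduced
    emergency-department (ED) attendance during pandemic waves. The core is a
    two-stage least squares (2SLS) estimator that instruments daily ED visit
    counts with binary wave-period indicators, adjusts for seasonality with
    polynomial day-of-year and year terms, supports lagged outcomes and
    weak-instrument partial-F diagnostics, and aggregates stratum-level local
    average treatment effects into total excess deaths. Includes cohort ETL
    (28-day mortality tallies by last visit date, COVID-positive exclusion,
    stratum filtering), descriptive avoidance analytics (seasonally adjusted
    period changes, death-on-arrival breakdowns, individual incidence-rate
    comparisons with two-sample z tests), Deyo-Charlson comorbidity mapping
    from ICD-9-CM codes, and a synthetic visit-record generator with known
    causal ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
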