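Package: gbmcea
Title: Markov Cohort Cost-Effectiveness Analysis of First-Line Glioblastoma Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (disease-free, progressed, dead) monthly Markov cohort
    model comparing radiotherapy alone, radiotherapy plus nitrosourea and
    radiotherapy plus temozolomide as first-line strategies for newly diagnosed
    glioblastoma, from a healthcare-system perspective over a five-year horizon.
    Provides Weibull survival calibration to Kaplan-Meier coordinates, indirect
    comparison via proportional-hazards scaling, a three-step imputation of
    missing subgroup progression-free survival, treatment-schedule costing with
    body-surface-area dosing, quality-adjusted life-year accrual with a monthly
    progressed-state utility decrement, incremental cost-effectiveness and
    dominance analysis, probabilistic sensitivity analysis with acceptability
    curves and confidence ellipses, one-way (tornado) sensitivity analysis, and
    validation of model medians against trial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    MASS,
    yaml,
    jsonlite
Suggests:
    flexsurv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
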