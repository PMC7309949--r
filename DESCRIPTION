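Package: nbdcea
Title: Cost-Effectiveness Modelling of Transanal Irrigation for Neurogenic
    Bowel Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of transanal irrigation (TAI) versus
    standard bowel care (SBC) for neurogenic bowel dysfunction after spinal
    cord injury, from the Japanese payer and societal perspectives.  Provides
    a six-state Markov cohort engine with half-yearly cycles and lifetime
    horizon, QALY and cost accrual with discounting, incremental
    cost-effectiveness ratios with dominance handling, mapping of the
    Neurogenic Bowel Dysfunction score (NBDS) to EQ-5D-5L utilities via
    per-dimension multinomial logistic regression and Monte Carlo profile
    simulation, derived clinical-risk estimators (relative risks, exponential
    stoma incidence, nursing-visit logistic model), a human-capital
    productivity-loss scenario, one-way (tornado) and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and a
    synthetic patient-survey generator for end-to-end testing of the fitting
    stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
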