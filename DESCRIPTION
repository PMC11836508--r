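Package: netcohort
Title: Comparative-Safety Cohort Studies Across Observational Database Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end engine for active-comparator new-user cohort
    studies run across a network of heterogeneous observational health
    databases. Provides a synthetic multi-database generator with known
    ground truth (confounding, true hazard ratios, injectable systematic
    bias), eligibility and time-at-risk cohort construction, large-scale
    L1-regularized propensity-score matching with covariate-balance and
    empirical-equipoise diagnostics, Cox proportional-hazards estimation
    with partial-likelihood profiles, empirical calibration of estimates
    and p-values against negative-control outcomes (including the expected
    absolute systematic error statistic), objective diagnostic gating, and
    Bayesian random-effects meta-analysis on non-normal likelihood
    approximations. Results are tibbles; fitted objects have tidy() and
    glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
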