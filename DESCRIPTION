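Package: countyrank
Title: Empirical Bayes Rank Uncertainty for County Health Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the precision of county health rankings built from
    composite health-outcome scores. Fits two-level (state, county-within-state)
    mixed models to five county health-outcome measures -- age-group mortality
    (Poisson), low birth weight and self-reported fair/poor health (binomial),
    and mean poor physical and mental health days (log-normal with known
    sampling variances) -- then applies empirical Bayes conditioning to draw
    joint posterior samples of county-level values, builds the weighted
    composite z-score used for health-outcome ranking (including the YPLL-75
    premature-mortality metric reconstructed from age-specific rates), and
    reports rank point estimates, central 90% rank credible intervals,
    quartile-membership probabilities, and posterior predictive model checks
    based on the across-county interquartile range. Includes a synthetic
    county-universe generator with known truth, small-count suppression and
    survey censoring, so calibration of the rank intervals can be verified.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    lme4,
    metafor,
    Matrix,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
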