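Package: lscmatch
Title: Large-Scale Cardinality and Propensity Score Matching with
    Empirical Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing and evaluating large-scale matched
    comparative cohort studies. Implements cardinality matching, which
    solves a mixed-integer program for the largest 1:1 matched sample
    satisfying prespecified standardized-mean-difference balance
    constraints (including exact fine balance), alongside greedy 1:1
    propensity-score matching on the logit scale with a caliper.
    Propensity models are L1-penalized logistic regressions over
    high-dimensional sparse covariates with cross-validated tuning, and
    covariates with non-zero coefficients define the matching-covariate
    set. Residual confounding after matching is quantified with negative
    control outcomes through an empirical-null systematic error model
    (expected systematic error with MCMC credible intervals), and outcome
    hazard ratios are calibrated against that null. A seeded synthetic
    new-user cohort generator with confounded treatment assignment and
    survival outcomes supports end-to-end evaluation across stratified
    subsample draws.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    glmnet,
    survival,
    reticulate,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
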