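Package: rpmlogit
Title: Random-Parameters Multinomial Logit Models for Seasonal Crash Injury Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of random-parameters (mixed) multinomial logit models
    with heterogeneity in the means and variances of the random coefficients,
    by simulated maximum likelihood with Halton draws. Designed for
    casualty-level crash injury-severity analysis with a three-level outcome
    (minor, severe, fatal): includes a validated casualty-record container
    with seasonal partitioning, a seeded synthetic-data generator emulating
    police-registry covariate structure, average marginal effects for
    indicator covariates, random-parameter distributional summaries,
    chi-square seasonality tests, and pairwise likelihood-ratio
    transferability and temporal-stability tests between fitted models.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
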