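Package: vepvuln
Title: Household Health Poverty Vulnerability via Expected-Poverty Estimation
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures household vulnerability to health-related poverty from a
    single cross-sectional survey using the vulnerability-as-expected-poverty
    (VEP) framework with a three-stage feasible generalized least squares
    estimator of the conditional mean and variance of log income. Provides
    quantile-regression heterogeneity analysis with cross-quantile Wald tests
    and V / inverted-V shape classification, recursive composite path models
    with standardized direct/indirect/total effect decomposition and
    covariance-based fit indices, a seeded synthetic household-survey
    generator with known ground truth, and a command-line pipeline tying the
    stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
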