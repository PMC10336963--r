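Package: adduq
Title: Noise, Bias and Variance Diagnostics for Molecular Property Models on
    Exact Group-Additivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds synthetic molecular datasets whose enthalpy targets are
    exact sums of Benson-style group increments (central heavy atom plus its
    1-bond-radius environment), so that a surrogate regressor can in principle
    be driven to zero error. Controlled random or systematic noise is then
    injected, desk-scale surrogates and deep-ensemble analogues are trained,
    and the observed test error is decomposed into noise, bias (nonvariance)
    and variance contributions via empirical-Bayes inference on the ensemble
    spread. Includes mean-variance estimation (heteroscedastic) surrogates,
    confidence-based calibration curves with the area under the calibration
    error curve (AUCE), sharpness/dispersion diagnostics, size-extrapolation
    experiments contrasting sum and mean atomic aggregation, and deliberate
    train/test contamination experiments quantifying perceived versus true
    error under data leakage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
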