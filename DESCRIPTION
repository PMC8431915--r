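Package: ordnet
Title: Regularized Partial Correlation Networks for Ordinal Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and robustness analysis of Gaussian graphical models
    for ordinal questionnaire items. Implements graphical lasso estimation on
    nonparametric Spearman correlations with extended BIC model selection,
    expected influence and bridge expected influence centralities over an
    a-priori two-community partition, nodewise predictability, nonparametric
    and case-dropping bootstrap diagnostics with the correlation-stability
    coefficient, and a latent-Gaussian threshold simulator for ordinal item
    responses with a known sparse ground-truth network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
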