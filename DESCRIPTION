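Package: isingnet
Title: Ising Network Analysis of Binary Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and analysis of Ising networks for binary
    questionnaire items: nodewise l1-regularized logistic regression with
    extended-BIC model selection (the eLasso estimator), strength, expected
    influence and bridge expected influence centralities over item
    communities, case-dropping and nonparametric bootstrap stability
    (correlation stability coefficient, edge confidence intervals),
    simulated node interventions by threshold perturbation with Gibbs
    sampling of network sum scores, and permutation-based two-group network
    comparison. Includes a synthetic-data generator with exact small-network
    enumeration and threshold calibration, a codebook-driven recoding layer
    for yes/no, know/don't-know and dichotomized 4-point Likert items, and
    network serialization to edge-list CSV, GraphML and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
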