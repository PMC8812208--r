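Package: costnet
Title: Patient-Level Healthcare Cost Prediction from Longitudinal Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts one-year future healthcare costs at the patient level
    from longitudinal insurance-claims records. Provides a seeded synthetic
    claims simulator (quarterly coded events, seven sectoral cost categories,
    zero-inflated heavy-tailed costs, planted 100-fold cost-change events),
    quarterly one-hot featurization with rare-code filtering, four predictors
    (last-year and mean-of-previous baselines, multivariate ridge regression,
    and a skip-connection multilayer perceptron trained with ADAM), ensemble
    averaging, an evaluation suite (Pearson and Spearman correlation, MAE,
    R-squared, Cumming's Prediction Measure, precision-recall and ROC curves
    for detection of patients with more than 100-fold cost changes, error-by-
    cost profiles, training-size by observation-length sensitivity grids),
    and integrated-gradients feature attribution with abundance normalization
    and per-quarter aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
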