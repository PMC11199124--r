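Package: mlkrige
Title: Hybrid Machine-Learning Residual Kriging for Spatial Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial prediction of point-referenced continuous responses by
    hybridizing machine-learning trend models with ordinary kriging of their
    residuals. Implements boosted-regression-tree residual ordinary kriging
    (BRTOK) and LASSO residual ordinary kriging (LASOK) together with the
    plain ordinary-kriging and boosted-tree baselines, empirical
    semivariogram estimation with spherical-model fitting, local-neighborhood
    kriging with prediction variance, k-fold cross-validation with grid
    search and paired t-test model comparison, variable-importance ranking,
    and a synthetic spatial-data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
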