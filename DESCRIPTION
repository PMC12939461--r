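Package: rankstab
Title: Stability Benchmarking of Feature-Importance Rankings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Benchmarks the stability of feature-importance rankings on
    high-dimensional tabular (multi-omics style) data. Provides seven
    pluggable importance scorers (ordinary least squares and LASSO
    coefficient magnitudes, random-forest Gini importance, gradient-boosted
    tree gain, PCA loading sums, feature-wise variance, and absolute
    Spearman correlation), a leave-top-feature-out perturbation protocol
    with a strict order-preservation consistency criterion, overlap-based
    contrast metrics, a leakage-safe stratified cross-validation harness
    for downstream predictive evaluation, and a synthetic data generator
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
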