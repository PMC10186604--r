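Package: ratioAge
Title: Ratio-Layer Neural Networks for Metabolomic Age Prediction from
    Untargeted LC-MS Feature Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting chronological age from untargeted LC-MS
    metabolomics feature tables that lack pooled quality controls. Implements
    a feed-forward neural network whose second layer forms all unique pairwise
    ratios of a small compression layer, exploiting the scale-cancelling
    property of compound ratios to absorb dilution and batch effects without
    an explicit normalization step. Includes the surrounding pipeline:
    fourth-root transformation, batch-wise missingness filtering, PCA outlier
    removal, robust-rank row normalization, quantile normalization, data
    partitioning, a normalization-by-learner screening harness with bootstrap
    RMSE comparison, ensemble training with averaged predictions,
    ensemble-averaged Shapley attributions with variance-based global
    importance, Spearman/Benjamini-Hochberg univariate screening, and a
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    data.table,
    jsonlite,
    yaml,
    glmnet,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
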