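Package: bofs
Title: Bayesian-Optimized Hyper-Parameter Tuning for High-Dimensional
    Feature Selection
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying whether Bayesian optimization of
    hyper-parameters improves feature selection on high-dimensional
    molecular data. Provides a synthetic-data generator for sparse linear
    and non-linear outcome models, a Gaussian-process Bayesian optimizer
    with upper-confidence-bound acquisition, six feature selectors
    (lasso, elastic net, gradient boosting, sure independence screening,
    minimum-redundancy-maximum-relevance, sparse partial least squares
    discriminant analysis) with Bayesian-optimized, AIC, cross-validated
    and default tuning variants, and a recall-rate benchmark plus a
    train/test prediction stage for downstream evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    xgboost,
    e1071,
    randomForest,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
biocViews: FeatureExtraction, Regression, DimensionReduction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
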