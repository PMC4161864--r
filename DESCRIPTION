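Package: mirUDB
Title: Validation of Fixed Blood miRNA Biomarker Panels Against
    Data-Driven Feature Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking a fixed ("universal") blood miRNA
    biomarker panel against features selected by PCA-based unsupervised
    feature extraction or by the LARS-lasso path, when discriminating
    patients from healthy controls under leave-one-out cross-validation.
    Provides per-sample z-score normalization of expression matrices,
    the dual PCA embedding of miRNAs and samples with outlier-based
    unsupervised feature selection, semi-supervised PCA-based linear
    discriminant analysis, Gaussian-kernel support vector classification
    with class rebalancing, lasso-path discrimination with a numeric
    1/2 response and a 1.5 decision cut, a selection-stability statistic
    over cross-validation folds, per-miRNA Welch t-tests with
    Benjamini-Hochberg adjustment, confusion-table metrics (Fisher exact
    test, odds ratio, ROC AUC), and a synthetic two-group cohort
    generator for desk-scale evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    MASS,
    e1071,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'mirUDB-package.R'
    'AllGenerics.R'
    'MirnaExperiment-class.R'
    'lars.R'
    'pca-fe.R'
    'classifiers.R'
    'cross-validation.R'
    'evaluation.R'
    'expression-io.R'
    'reference-data.R'
    'simulate.R'
    'stability.R'
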