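Package: imbcart
Title: Resampling Methods and Classification Trees for Class-Imbalanced
    Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how resampling a class-imbalanced
    binary-outcome cohort changes the predictive power of tree-based
    classifiers. Provides a synthetic low-prevalence cohort generator,
    random oversampling, random undersampling and class weighting at
    configurable case-to-control ratios, a from-scratch implementation of
    classification trees (Gini impurity split search, cost-complexity
    pruning, cross-validated complexity selection by the 1-SE rule),
    bagged and boosted tree ensembles built on the same engine, a
    test-set metric battery (AUC, sensitivity, specificity, PPV, NPV,
    classification rate), and a driver that runs the full
    resampling-by-model experiment grid.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
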