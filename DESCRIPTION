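Package: velodirect
Title: RNA Velocity Direction Classification with Cascade Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates per-cell RNA velocity from paired spliced and
    unspliced count matrices under a steady-state ratio model and a
    dynamic kinetic model fit by expectation maximization, discretizes
    the 2D-projected velocity direction into equal angular classes, and
    predicts those classes from gene expression with a cascade forest: a
    layered ensemble of heterogeneous tree learners whose out-of-fold
    class-probability vectors augment the features of the next level.
    Includes a kinetic simulator with ground-truth directions, tiered
    highly-variable-gene selection, k-nearest-neighbour moment smoothing,
    SMOTE-Tomek resampling and confusion-matrix metrics (accuracy,
    macro-F1, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    randomForest,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
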