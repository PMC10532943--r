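Package: markerIFS
Title: Marker-Gene Discovery for Labeled Single-Cell Expression Data by
    Incremental Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the genes of a labeled cells-by-genes expression matrix by
    five complementary schemes (one-vs-rest lasso coefficients, split counts
    of a gradient-boosted tree ensemble, Monte Carlo feature selection,
    minimum-redundancy maximum-relevance mutual information, and random-forest
    impurity importance), then locates compact discriminative gene subsets by
    incremental feature selection: growing prefixes of each ranked list are
    scored with stratified cross-validated decision-tree and random-forest
    classifiers, with SMOTE oversampling of minority cell types inside each
    training fold. Reports accuracy, the multiclass Matthews correlation
    coefficient, and macro/weighted F1; distills quantitative cell-type
    classification rules from decision trees as root-to-leaf threshold paths;
    and ships a synthetic-data generator with planted class-specific marker
    genes and heavy class imbalance so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    glmnet,
    jsonlite,
    methods,
    ranger,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
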