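Package: geneximb
Title: Imbalance-Aware Classification of Gene-Expression Microarrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for cancer classification from gene-expression microarray
    data under severe class imbalance and high dimensionality. Implements
    the SMOTE family of minority oversamplers (plain, Borderline B1/B2,
    SVM-guided and k-means cluster-based) with a balance-to-majority
    planning rule and exact per-sample provenance; chi-square and
    information-gain gene ranking on entropy/MDL-discretized expression
    with an intersection-based combined selector (ChiSIG); a homogeneous
    1/3/5-nearest-neighbour majority-voting ensemble plus configurable
    ensemble-learning backends; and leakage-safe holdout and stratified
    cross-validation harnesses reporting weighted precision, recall, F1 and
    accuracy. A synthetic-data generator produces imbalanced
    microarray-like benchmarks with known informative genes so the whole
    pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    foreign,
    jsonlite,
    nnet,
    randomForest,
    rpart,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
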