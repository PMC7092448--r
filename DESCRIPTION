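Package: sssHD
Title: Stable Sparse Feature Selection for Class-Imbalanced Data via the
    Hellinger Distance
Version: 0.1.0
Authors@R:
    person("sssHD", "Developers", email = "ssshd@example.org",
           role = c("aut", "cre"))
Description: Feature selection for high-dimensional binary classification
    problems with severe class imbalance, such as gene-expression biomarker
    screening. Implements an embedded selector that tunes an elastic-net
    penalized linear support vector machine by maximizing the Hellinger
    distance between the decision-score distributions of the two classes,
    a criterion that is insensitive to the class-imbalance ratio and to
    shifts of the decision scores. Stability selection over stratified
    subsamples yields per-feature inclusion frequencies and a ranking.
    Also provides classical filter baselines (Fisher score, Relief,
    per-feature ROC and precision-recall areas), imbalance-aware
    evaluation metrics (G-mean, F-measure, lower-trapezoid AUCROC),
    SMOTE oversampling, stratified resampling protocols, and a
    blocked-covariance Gaussian simulation harness for benchmarking
    selection criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
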