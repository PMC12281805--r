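Package: topogen
Title: Topological Descriptors of Molecular Feature Spaces and
    Generalization-Error Meta-Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes Vietoris-Rips persistent homology (homological
    dimensions 0 and 1) of molecular-representation feature spaces, turns
    persistence diagrams into one-dimensional descriptor vectors (Betti
    numbers, lifetime/midlife statistics, persistence entropy), estimates
    intrinsic dimension (TwoNN, local PCA, persistent-homology dimension),
    and computes QSAR activity-landscape modelability baselines (SALI, SARI,
    RMODI, ROGI and its cluster-count variant). A benchmarking layer trains
    random-forest and neural-network regressors on labelled feature matrices
    with grid-search cross-validation and min-max error normalization, and a
    meta-model layer fits a clipped random-forest regressor that predicts
    the normalized generalization error from the topological descriptors,
    evaluated by leave-one-dataset-out and leave-one-representation-out
    cross-validation. Seeded synthetic generators (point clouds of known
    topology, fingerprint-like bit matrices, property landscapes with
    planted activity cliffs) make every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
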