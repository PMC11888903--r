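Package: phca
Title: Persistent Homology Classification of Landmark Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topology-based classification of labelled point clouds with the
    Persistent Homology Classification Algorithm (PHCA). A query point is
    assigned to the class whose total persistent-homology lifespan changes
    least when the point is inserted into the class cloud. Includes a
    Vietoris-Rips persistence engine (radius convention, fast H0 path via
    minimum spanning trees, brute-force boundary-matrix oracle), a full
    evaluation harness (stratified splitting, standard scaling, random-search
    hyperparameter tuning with stratified k-fold cross-validation, macro
    metrics, confusion and misclassification reports, multi-trial
    orchestration against classical baselines), Friedman and Nemenyi
    classifier comparison with the critical-difference statistic, a synthetic
    hand-landmark data generator, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    e1071,
    ranger,
    rpart,
    class
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
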