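Package: switchconn
Title: Task-Based Functional Connectivity, Classification, and Network
    Efficiency for Cued Task-Switching Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing task-based functional connectivity in
    two-group (case-control) cued task-switching fMRI studies. Implements
    single-trial response estimation with the least-squares-separate GLM,
    beta-series Pearson correlation connectomes, connectome-based group
    classification with F-score feature ranking, a linear max-margin
    classifier under leave-one-out cross-validation with a feature-count
    sweep and a label-permutation significance test, and weighted-graph
    analysis of network integration and segregation (global and local
    efficiency) summarised across a sparsity-threshold sweep. A seeded
    synthetic-data generator emulates cued task-switching designs and
    modular, group-structured trial-wise responses so the full pipeline
    can be exercised and tested without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
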