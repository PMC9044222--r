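Package: mmpso
Title: Hybrid MIC-mRMR Filter and Particle Swarm Wrapper Feature Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature selection for high-dimensional labelled tabular data,
    aimed at gene-expression biomarker discovery. Features are first ranked
    by a minimum-redundancy maximum-relevance (mRMR) filter whose association
    measure is the maximal information coefficient (MIC), then a particle
    swarm optimization (PSO) wrapper searches subsets of the top-ranked
    features under a cost that combines k-nearest-neighbour
    cross-validation error with a subset-size penalty. Includes class
    balancing by random oversampling, sparse-feature filtering, SVM
    cross-validation and logistic biomarker-panel scoring with ROC/AUC for
    validating the selected panel, and seeded synthetic-data generators with
    planted ground truth for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    e1071,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    SummarizedExperiment,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: FeatureExtraction, Classification, GeneExpression, Transcriptomics
RoxygenNote: 7.3.3
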