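Package: deepdra
Title: Multi-Task Autoencoder Model for Drug Response Prediction and Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary drug sensitivity of cancer cell lines from
    multi-omics profiles (gene expression, mutation, copy number, optionally
    methylation) and drug structure (molecular descriptors and circular
    fingerprints computed from SMILES). Two autoencoders compress the
    cell-line and drug feature vectors; their latent representations feed a
    multilayer-perceptron classifier, and all three parts are trained jointly
    under a composite reconstruction-plus-classification loss. Includes
    per-cohort binarization of continuous response measurements, stratified
    splitting, k-fold and cross-cohort evaluation with precision-recall
    metrics, drug-repurposing score ranking, and a latent-factor synthetic
    cohort generator for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
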