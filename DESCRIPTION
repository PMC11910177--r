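Package: seqmoments
Title: Moment-Based DNA Sequence Encoding and Ensemble Classification of
    Driver Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes DNA sequences into a fixed 522-coefficient feature
    vector built from raw, central and discrete Hahn moments of
    two-dimensional sequence representations, position relative incidence
    matrices (PRIM/RPRIM) over mono-, di- and tri-nucleotides, k-mer
    frequency vectors and accumulative absolute position incidence
    vectors (AAPIV/RAAPIV).  Trains and validates tree-ensemble
    classifiers (random forest, gradient boosting, extremely randomised
    trees, bagging, stacking) with the protocols used for sequence-based
    predictors: self-consistency, repeated independent train/test splits
    and stratified k-fold cross-validation, reporting accuracy,
    sensitivity, specificity, Matthews correlation coefficient and ROC
    curves.  Includes a synthetic two-class sequence generator with
    controllable k-mer enrichment for download-free benchmarking, CSV
    feature-table persistence and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    glmnet,
    graphics,
    grDevices,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
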