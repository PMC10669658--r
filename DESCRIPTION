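Package: one2mfusion
Title: Gene-Expression-to-Image Fusion Networks for Transcriptomic Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the One2MFusion approach to transcriptomic
    classification: discriminative genes are selected by L1-penalised
    (LASSO) regression, scored by the two-class Fisher criterion, binned
    into equal-count categories, and placed in a two-dimensional plane by
    linear discriminant analysis on genes-as-observations; the point cloud
    is tightened by the minimum-area enclosing rectangle and rasterised so
    every sample becomes a small grayscale image. Samples are then
    classified by a feed-forward network on the expression vector, a
    convolutional network on the gene image, and a late-fusion joint
    network that concatenates both feature vectors. Includes a synthetic
    multi-dataset cohort simulator with planted differential expression
    and batch effects, GEO series-matrix ingestion, per-dataset
    standardisation with cohort-wide min-max merging, stratified
    five-fold cross-validation with AUC/ROC reporting, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    glmnet,
    data.table,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    optparse,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
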