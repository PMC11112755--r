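Package: crossomix
Title: Multiomic Analysis of Crossover Exposure Studies with
    Stability-Calibrated Networks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end statistical analysis of repeated-measures crossover
    exposure studies with omics readouts. Provides a synthetic-data generator
    emulating a two-site, three-occasion crossover design with correlated
    features, batch effects and left-censored missingness; preprocessing
    (missingness filtering, log2 transform, QRILC imputation of left-censored
    values, PCA outlier flagging, mixed-model subtraction of technical batch
    effects); per-feature repeated-measures multivariate-normal (GLS)
    association testing with unstructured occasion covariance and
    effective-number-of-tests Bonferroni correction; stability-calibrated
    consensus clustering with medoid extraction; graphical-LASSO
    conditional-independence networks calibrated by stability over subsamples,
    including multi-block (multiomic) penalties and cross-time rewiring
    comparison; and m/z adduct matching with Fisher-exact over-representation
    analysis against user-supplied pathway maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metabolomics, Transcriptomics, Network, GraphAndNetwork,
    Clustering, BatchEffect, Preprocessing
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'synthdata.R'
    'preprocess.R'
    'association.R'
    'clustering.R'
    'network.R'
    'enrichment.R'
    'pipeline.R'
    'crossomix-package.R'
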