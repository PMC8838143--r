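Package: lcnet
Title: Lightweight Convolutional Network for Dermoscopic Melanoma Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for binary melanoma-versus-benign classification
    of dermoscopic skin-lesion images with LCNet, a lightweight multi-block
    convolutional neural network built from parallel 1x1/3x3 branches joined by
    channel concatenation. Provides manifest handling with stratified
    train/validation/test splitting, duplicate-image elimination by grayscale
    Pearson correlation, center-crop and bilinear-resize preprocessing, class
    balancing by random oversampling with online affine augmentation, SGDM
    training with weighted cross-entropy and early stopping, confusion-matrix
    metrics with ROC/AUC reporting, and a seeded generator of lesion-like
    synthetic images so that every stage is testable without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
biocViews: Classification, Software
RoxygenNote: 7.3.3
Collate: 
    'lcnet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'dataio.R'
    'dedupe.R'
    'preprocess.R'
    'augment.R'
    'architecture.R'
    'network.R'
    'train.R'
    'evaluate.R'
    'synthgen.R'
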