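Package: calcamdf
Title: Calcification Classification on Magnification Mammograms with
    Adaptive Multiscale Decision Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully tested re-implementation of a deep-learning
    pipeline for classifying breast calcifications on spot magnification
    mammograms: mask-overlap contrast preprocessing (median filter, gamma
    correction, white top-hat segmentation, mask superimposition), a small
    single-stage pyramid detector whose three scale heads are combined by an
    adaptive multiscale decision fusion (AMDF) layer with softmax-normalised,
    backprop-learned reliability weights, and a mixed-input multilayer
    perceptron ensemble that merges detector confidence scores with
    radiologist-style morphology/distribution descriptors and standardized
    clinical covariates. A synthetic mammography-phantom generator provides
    case rosters and images with ground-truth boxes so the whole pipeline is
    reproducible without clinical data. Evaluation utilities cover case-level
    train/test splitting, Monte-Carlo cross-validation, ROC/AUC analysis with
    optimal-cutoff selection and confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
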