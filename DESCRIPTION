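Package: echoflow
Title: Regional Wall Motion Abnormality Detection from Multi-View
    Echocardiography Motion Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase pipeline for detecting regional wall motion
    abnormalities (RWMA) in apical two-chamber and four-chamber
    echocardiogram loops: U-Net segmentation of the left-ventricular wall,
    segmentation-masked dense optical flow over multiple cardiac cycles,
    snippet-based temporal convolutional feature extraction with segmental
    consensus, and a multi-view classifier bank evaluated under stratified
    k-fold cross-validation. Includes a synthetic beating-heart phantom
    generator with ground-truth wall masks and per-segment motion
    amplitudes, so every stage is testable end to end, plus left-ventricular
    contour partitioning and per-segment displacement curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    class,
    rpart,
    randomForest,
    e1071,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
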