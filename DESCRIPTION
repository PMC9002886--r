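Package: skelgait
Title: Skeleton-Based Gait Recognition with a Residual Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end person identification from Kinect-style 3D skeleton
    sequences. Gait cycles are segmented from the smoothed inter-ankle distance
    signal, each cycle is turned into a frames-by-joints-by-coordinates tensor,
    and a compact residual convolutional network with global average pooling
    classifies cycles by subject without resampling variable-length cycles to a
    fixed size. Includes subject-wise five-fold cross-validation, a biometric
    metric suite (accuracy, macro precision/recall/F-score, CMC curve,
    macro-averaged ROC with normalized AUC, equal error rate), a parametric
    synthetic walker for fully reproducible experiments, and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
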