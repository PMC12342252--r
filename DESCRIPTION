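Package: tapkin
Title: Video-Derived Finger-Tapping Kinematics for Bradykinesia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bradykinesia from video-derived hand-landmark
    time series of the finger-tapping test. Converts 21-point hand-landmark
    streams to normalized thumb-index amplitude signals, detects taps by
    topographic peak prominence, extracts per-hand and per-subject kinematic
    features (tap count, amplitude mean/variation, amplitude decrement,
    inter-hand asymmetry), and evaluates bradykinesia classifiers under nested
    stratified cross-validation with t-based confidence intervals and
    Monte-Carlo Shapley feature attributions. Includes a synthetic tapping
    simulator with control and Parkinsonian presets for end-to-end testing and
    parameter-recovery studies, plus consensus-label construction and
    Krippendorff's alpha inter-rater agreement with bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
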