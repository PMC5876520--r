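Package: motionseg
Title: On-Line Detection and Phase Segmentation of Sports Motions from a
    Wearable Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects occurrences of a modeled sports motion in a continuous
    100 Hz six-channel inertial (IMU) stream and localizes every phase
    boundary to a single frame. A motion is declared as an ordered chain of
    sub-motions whose start/performing/end states share single-frame
    boundaries. Raw acceleration and angular-velocity samples are converted
    to 11-element per-sample feature vectors, labeled per timestep by a
    small bidirectional GRU sequence classifier trained with
    class-imbalance-weighted cross-entropy, accumulated on-line, matched
    against the motion model's state pattern, and segmented by a dynamic
    program over boundary-state probabilities. Includes a seeded synthetic
    IMU generator so training and evaluation run without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
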