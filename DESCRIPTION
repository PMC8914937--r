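Package: imucanvas
Title: Deterministic Image Encodings of Inertial Sensor Time Series for
    Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes windows of multivariate inertial-sensor (IMU) time
    series as small raster images by a deterministic, training-free
    procedure: each window is summarised by simple patterns over time
    (oscillatory variation, steady variation, and range), the pattern
    values are mapped to numbers of marked pixels inside dedicated canvas
    regions, and the pixels are marked continuously along deterministic
    filling paths (spirals, diagonals, strokes).  Optional colour schemes
    encode neighbouring time windows or multiple sensors on the RGB
    channels, and several sensors can be tiled onto an augmented canvas.
    A compact reference convolutional network (two 128-filter 3x3
    convolution + max-pool blocks, a 256-unit dense layer and a softmax
    output, trained with cross-entropy, Adam and early stopping) is
    included so activity recognition can be run end to end, together with
    a synthetic labelled IMU generator, stratified evaluation protocols
    and per-class classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
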