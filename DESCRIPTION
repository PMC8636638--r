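Package: deepcount
Title: Count Regression from Image-Level Labels with Noisy-Label Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting objects in raster images from image-level integer
    labels alone: a compact convolutional count regressor trained with the Huber
    loss, two-phase transfer-style training with discriminative layer-wise learning
    rates and a one-cycle schedule, stratified label-binned test-set construction,
    label-preserving augmentation, a two-step active refinement loop for noisy
    (undercounted) labels, gradient-weighted class-activation heatmaps for the
    regression output, and seeded synthetic benchmarks (dot-field scenes emulating
    aerial wildlife survey photographs and concentric-ring images emulating otolith
    micrographs) so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    withr,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    jsonlite
Config/testthat/edition: 3
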