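Package: dsaclust
Title: Quantitative Cluster Analysis of Digital Subtraction Angiography Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments 8-bit grayscale angiography frames into four intensity
    clusters (background, low, medium, high) by globally minimizing the
    within-cluster sum of squares with a symmetric DIRECT (dividing
    rectangles) optimizer, then quantifies pre- versus post-treatment pixel
    redistribution per cluster and runs the paired and between-group
    nonparametric statistics of a cohort report. Includes an exact
    one-dimensional k-means dynamic-programming oracle for optimizer
    verification, a synthetic vascular phantom generator with ground-truth
    labels, and an end-to-end cohort pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
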