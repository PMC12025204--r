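Package: lesionlab
Title: Skin-Lesion Image Classification with Autoencoder Features and
    Quantum-Kernel Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for multi-class
    pigmented skin-lesion classification. Provides formula-exact image
    enhancement (multi-scale retinex, gamma correction, histogram
    equalization, unsharp masking, CLAHE), GAN-based minority-class
    balancing, a convolutional autoencoder feature extractor with
    reconstruction-error anomaly detection and 4x super-resolution
    decoding, a classically simulated second-order-expansion quantum
    kernel and polynomial kernel one-vs-rest soft-margin SVM classifier,
    Grad-CAM saliency maps, confusion-matrix metrics, and a synthetic
    lesion-image generator so the whole pipeline runs without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    Rcpp,
    generics,
    ggplot2,
    kernlab,
    png,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    e1071,
    withr,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
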