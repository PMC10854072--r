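Package: mducnn
Title: Multi-Dimensional U-Shaped Convolutional Networks for Biomedical
    Image Segmentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction, training and evaluation of multi-dimensional
    U-shaped convolutional networks (MDU-CNN) for binary semantic
    segmentation of 2D biomedical images and multi-channel 3D volumes,
    together with a matched baseline U-Net. Multi-dimensional blocks
    factorise large receptive fields into chained 3x3 convolutions with a
    1x1 residual projection; residual convolution paths along the skip
    connections reduce the semantic gap between encoder and decoder
    features. Includes the per-level filter-width calculus, per-layer
    parameter accounting, pixelwise binary cross-entropy training with
    adaptive moment estimation, Jaccard-index evaluation, k-fold
    cross-validation with best-on-test tracking, flip/rotation data
    augmentation, ablation variants, and a seeded synthetic-data generator
    emulating five biomedical imaging challenges (fluorescence microscopy,
    endoscopy, dermoscopy, electron microscopy, multi-channel MRI).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    Rcpp,
    EBImage,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
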