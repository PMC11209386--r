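Package: pcamseg
Title: Pyramid Channel Attention U-Net for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segmentation of retinal blood vessels in colour fundus images
    with a U-shaped encoder-decoder that combines a pyramid channel
    attention module (spatial pyramid max-pooling followed by shared-MLP
    channel gating) with pre-activated residual convolution blocks
    regularised by DropBlock. Provides the network and its building blocks
    with exact forward/backward passes, a synthetic vessel-phantom
    generator with pixel-exact ground truth, loaders for DRIVE/CHASE_DB1/
    STARE-style dataset layouts including field-of-view mask estimation,
    patch-based inference with overlap averaging, the standard confusion
    metric suite (IOU, accuracy, sensitivity, specificity, F1), and a
    small training/evaluation/ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
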