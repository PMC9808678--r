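Package: munet
Title: Multi-Output U-Net for Joint Lung Segmentation and Classification
    with Mask-Cropped Grad-CAM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains a multi-output U-Net that produces a binary
    lung segmentation map and a disease-class probability vector from a single
    shared convolutional encoder, entirely on the CPU with no external deep
    learning framework. Includes a deterministic synthetic chest-phantom
    generator with exact ground-truth lung masks, the full segmentation metric
    stack (Dice coefficient and loss, IoU, pixel accuracy, sparse categorical
    cross-entropy) computed from a single confusion-count core, a seeded
    batch-session training protocol with best-validation-loss checkpointing,
    hyperparameter sweep and activation-comparison harnesses, and a Grad-CAM
    explainability workflow in which the class-activation heatmap is cropped
    by the predicted lung mask before being overlaid on the input image.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tibble,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
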