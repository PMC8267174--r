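Package: slideheat
Title: Patch-Based Whole-Slide Image Tumor Detection via Probability-Heatmap Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a two-stage
    whole-slide-image (WSI) pipeline for pancreatic ductal adenocarcinoma
    (PDAC) detection. Slides are cut into 1,024-pixel patches, a small
    convolutional network scores each patch, the per-patch malignant
    probabilities are assembled into a slide heatmap, 36 summary statistics
    of the heatmap feed a gradient-boosted tree classifier for the
    slide-level call, and a U-Net trained with dice loss segments tumor
    regions from half-overlapping 256-pixel tiles. Includes Grad-CAM
    attention maps, a synthetic-slide generator with ground-truth polygon
    annotations so every stage runs without external data, and a full
    evaluation toolkit (confusion matrices, precision/recall/F1, ROC/AUC,
    dice). The network engine (convolutions, backpropagation, Adam) is
    implemented in base R and sized for laptop-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xgboost,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
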