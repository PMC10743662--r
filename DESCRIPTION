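Package: radwindow
Title: Learnable Intensity Windowing for High-Bit-Depth Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intensity windowing of high-bit-depth (12-bit)
    chest radiographs and for studying its effect on multi-label image
    classification. Provides the closed-form window operator and its
    clamped-affine (1x1 convolution) equivalent, fixed-window
    preprocessing with bit-depth reduction, a trainable multi-window
    front-end layer whose parameters encode window level and width and
    can be recovered after training, the accompanying training protocol
    (binary cross-entropy, AdamW, reduce-on-plateau, early stopping,
    checkpoint selection by validation AUC), per-class AUC evaluation
    with image-level nonparametric bootstrap confidence intervals, a
    fixed-window grid search with per-class window selection, and a
    synthetic 12-bit image generator whose class signals live in narrow
    intensity bands so that windowing demonstrably matters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
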