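Package: histogray
Title: Grayscale Conversion and Color-Variation Robustness Toolkit for
    Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a suite of grayscale conversion operators for
    hematoxylin-and-eosin (H&E) histopathology tiles, including the
    attention-based ACSRM operator that derives convex channel weights
    from a row-standardized softmax over the 3x3 channel Gram matrix.
    Provides Otsu-based tissue localization, conditional class-aware
    patch extraction with iterative target reduction and overlap
    fallback, flip-based class balancing, classification and
    segmentation metrics (precision, recall, F1, AUC, IoU, Dice), and
    paired model comparison statistics (exact and continuity-corrected
    two-tailed McNemar tests, exact and normal-approximation Wilcoxon
    signed-rank tests). A synthetic H&E phantom generator with ground
    truth label masks and simulated scanner/center color shifts makes
    every component testable without slide archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
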