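Package: lesionDx
Title: Skin-Lesion Segmentation and Diagnosis with SPF Level Sets and
    Hybrid Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A feature-based diagnosis pipeline for dermoscopy images of
    skin lesions. Lesions are delineated with a mask-restricted signed
    pressure force (SPF) level-set active contour that evolves inward from
    the image border, described by hybrid local binary pattern (LBP) and
    gray-level co-occurrence matrix (GLCM) texture features fused into a
    216-dimensional descriptor, and classified with a shallow multilayer
    perceptron. Includes a synthetic dermoscopy-image generator with known
    ground-truth masks, the full evaluation-metric suite (confusion matrix,
    per-class and macro accuracy/sensitivity/specificity/precision/F1,
    one-vs-rest ROC and AUC), and a command-line interface binding the
    stages into an end-to-end workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
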