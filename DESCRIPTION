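Package: lesionsnake
Title: Two-Step Lesion Segmentation and Characterization for Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments mass-like breast MRI lesions in two steps -- fuzzy
    c-means clustering for an initial region followed by a gradient vector
    flow (GVF) snake that refines the contour -- and characterizes the
    result with 13 gray-level co-occurrence (Haralick) texture features and
    8 radial-length/morphological shape descriptors. Includes area-overlap
    evaluation against reference masks, Fisher stepwise discriminant
    classification of benign versus malignant lesions with leave-one-out
    cross-validation, ROC/AUC analysis with the DeLong paired test, and a
    synthetic lesion-phantom generator for end-to-end testing without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    EBImage,
    pracma,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
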