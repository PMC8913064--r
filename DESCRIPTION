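Package: tumorseg
Title: Brain-Tumor Detection from Grayscale Images via Fuzzy C-Means,
    GLCM Texture Features and a Levenberg-Marquardt Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for detecting bright
    tumor-like lesions in 2-D grayscale brain images. Provides a seeded
    phantom simulator with exact ground truth, median-filter denoising and
    Canny edge localization, fuzzy c-means intensity clustering with the
    membership-change stopping rule, gray-level co-occurrence matrix
    (GLCM) texture features (contrast, homogeneity, correlation, energy)
    plus first-order intensity statistics, a small feed-forward classifier
    trained by Levenberg-Marquardt damped least squares (optionally tuned
    by accelerated particle swarm optimization), and confusion-matrix
    evaluation metrics on the percent scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    generics,
    rlang,
    ggplot2,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
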