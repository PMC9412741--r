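Package: elytra
Title: Species Identification of Pantry Beetles from Elytral Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for identifying food-contaminating
    (pantry) beetle species from photographs of their elytra, the
    hardened forewings whose surface pattern of striae and punctures is
    species-characteristic. The pipeline removes the white imaging
    background by detecting the elytral border, simulates physical
    fragmentation by sampling fixed-size tiles strictly inside the
    detected border, performs a leak-free image-level train/test split,
    trains a small convolutional neural network with a stochastic affine
    augmentation policy, and reports per-species one-vs-rest metrics
    (precision, recall, specificity, Matthews correlation coefficient)
    from tile-level confusion matrices. A procedural generator of
    synthetic elytra images with ground-truth masks and controllable
    intraspecies variation (maturity darkening, regional variegation,
    fibrous background interference) makes every stage testable without
    real specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    png,
    EBImage,
    jsonlite,
    yaml,
    readr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
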