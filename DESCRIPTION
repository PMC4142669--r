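Package: stereofiber
Title: Design-Based Stereology of Myelinated Nerve Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unbiased quantification of myelinated nerve fibers in transverse
    peripheral-nerve sections by design-based stereology. Implements systematic
    uniform random sampling of microscopy fields, edge-effect-free top-rule
    ("2D disector") counting in circular (light-microscopy) and rectangular
    (electron-microscopy) frames, circle-fitting morphometry (axon and fiber
    diameter, myelin thickness, g-ratio), density and total-fiber-number
    estimation, a resolution model for the systematic light-microscopy
    undercount of small fibers, and paired t-test group comparisons. A
    synthetic nerve cross-section generator with known ground truth (random
    sequential adsorption packing of non-overlapping fibers) supports
    validation of every estimator against the truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
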