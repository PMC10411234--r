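Package: realismeval
Title: Observer-Study Evaluation of Synthetic Medical Image Realism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of the realism of synthetic medical
    images with observer studies. Implements the ideal-observer
    (likelihood-ratio) framework linking two-alternative forced-choice
    (2-AFC) AUC to the Bhattacharyya distance between the distributions of
    real and synthetic images, including closed-form, quadrature and
    Monte-Carlo Bhattacharyya estimators and the erf-based AUC
    approximation. Also provides a local toolkit for 2-AFC expert-reader
    studies: session construction with shuffling and side randomization,
    response-log scoring with exact binomial inference, confidence-level
    tallies, System Usability Scale (SUS) scoring, and generators for
    synthetic image pairs and virtual readers so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
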