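Package: dmlc2d
Title: Leaf Sequencing and Delivery Analysis for a Two-Dimensional
    Dynamic Multileaf Collimator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for intensity-modulated radiotherapy (IMRT) leaf-motion
    calculation with a multileaf collimator (MLC) whose banks can translate
    perpendicular to leaf travel. Converts optimal fluence maps into
    sliding-window MLC control-point sequences, optimizes a rigid bank
    y-offset per fluence-map sector over sub-leaf-width candidates,
    reconstructs the actually deliverable fluence (analytically and with a
    brute-force time-stepped oracle), and evaluates conformity index, mean
    intensity, mean absolute difference and out-of-field area against
    conventional leaf-travel-only delivery, including paired statistics over
    case suites and a deterministic synthetic fluence-map generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
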