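Package: cellhota
Title: Cell-HOTA Evaluation of Cell Tracking with Division Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates cell-tracking results against ground truth with the
    Cell-HOTA metric, an extension of Higher Order Tracking Accuracy (HOTA)
    that scores detection, association, and cell-division accuracy across a
    sweep of mask-IOU similarity thresholds. Reads and writes Cell Tracking
    Challenge formatted sequences (per-frame integer label masks plus lineage
    tables), classifies division events as true/false positives with optional
    tolerance for divisions predicted one frame early or late, and ships a
    synthetic scenario generator with controlled perturbations so every metric
    behaviour can be verified against hand-computable expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    tidyr,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
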