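Package: msafilter
Title: Supervised Column Filtering for Multiple Sequence Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns a human annotator's multiple-sequence-alignment column
    filtering style from masked reference alignments and applies it to new
    alignments. A logistic model over six per-column features (gap
    proportion, percent identity, distance from the alignment extremity,
    Shannon entropy, and windowed gap proportions) is fitted by iteratively
    reweighted least squares; the decision threshold and sequence-bootstrap
    settings are calibrated on a validation set by the Matthews correlation
    coefficient (or accuracy, or an F-beta score); validated models are
    serialized as JSON and applied deterministically, with per-alignment
    confidence scores and full train/validate/test/filter tooling plus a
    synthetic-alignment generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
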