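Package: mirfom
Title: miRNA Hairpin Classification with Position-Specific Fixed-Order
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies candidate RNA hairpins as real or pseudo pre-miRNA
    precursors, locates the mature miRNA within the precursor, and calls the
    arm (5p, 3p or both) it occupies. Hairpin secondary structures are
    re-expressed in a six-symbol stem-bulge-gap alphabet, scanned with
    24-column sliding windows scored by a pair of position-specific
    fixed-order Markov models (log-odds of a true-precursor model against a
    pseudo-hairpin model), and combined with a logistic score over three
    minimum-free-energy indices (MFEI1, MFEI2, MFEI4). Includes seeded
    synthetic-hairpin generators so training, scanning and evaluation are
    testable without external downloads, plus k-fold cross-validation, ROC
    and mature-region localization metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
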