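Package: srda
Title: Single Residue Distribution Analysis for Mining Toxin-Like Precursors in EST Banks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts protein sequences into key-residue spacing patterns
    (Single Residue Distribution Analysis, SRDA), screens six-frame
    conceptual translations of expressed sequence tag (EST) banks with
    wildcard "screening line" motifs under stop-codon-bounded fragment
    rules, and calls secreted toxin-like precursors (signal peptide
    heuristic, propeptide cleavage, mature-domain deduplication). Ships
    the cysteine-scaffold motif registry for sea anemone toxins and a
    seeded synthetic EST bank generator so every pipeline stage is
    testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
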