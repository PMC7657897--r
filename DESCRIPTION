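Package: cpscan
Title: Degenerate E-Box Promoter Scanning and Carbamoyl-Phosphate
    Synthetase Functional Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two comparative sequence analyses of urea-cycle
    adaptation in extremophile tilapia: scanning promoter regions for
    degenerate, MyoD-preferred, paired and near-miss E-box motifs with
    TSS-relative coordinates and BED output; and classifying
    carbamoyl-phosphate synthetase (CPS) protein sequences into
    glutamine-utilizing, intermediate ammonia-preferring, or
    ammonia-obligate functional types from the states of the
    glutamine-amidotransferase catalytic triad (Cys-His-Glu) and two
    glutamine-binding residues mapped through a multiple alignment.
    Includes a global pairwise protein aligner for single-query
    classification, in-silico PCR amplicon prediction, and seeded
    synthetic-data generators with machine-readable truth files so every
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
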