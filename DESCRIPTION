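Package: promoterguide
Title: Promoter-Specific sgRNA Design for CRISPR Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs promoter-specific single-guide RNAs (sgRNAs) for
    CRISPR activation (CRISPRa) against genes with experimentally defined
    representative transcription start sites (TSSs). Computes strand-aware
    -50..-400 bp upstream promoter windows, enumerates 20-nt NGG-flanked
    protospacers on both strands, scores candidates with a pluggable
    position-weight logistic on-target model and a genome-wide
    mismatch-based specificity score, filters and ranks them, and exports
    ranked guide libraries. Also generates GC-balanced scramble controls
    with no genomic near-match, builds reproducible synthetic genome
    fixtures with planted off-targets, and simulates the sgRNA
    expression-vector cloning scheme (BioBrick backbone derivation,
    EcoRI/PstI cassette insertion, and BbsI/BsaI golden-gate spacer
    insertion with oligo design).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
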