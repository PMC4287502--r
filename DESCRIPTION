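Package: methalign
Title: Strand-Aware Bisulfite Read Alignment, Arbitration and Methylation Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for three-letter bisulfite sequencing
    alignment. Performs in-silico C-to-T / G-to-A conversion of genomes and
    reads (including reduced-representation genome digestion), aligns each
    read against every strand a library protocol permits, arbitrates between
    strand-specific candidate alignments with recalculated mapping qualities,
    assigns per-base methylation-call strings, extracts per-cytosine
    context-stratified methylation counts to bedGraph and R-friendly formats,
    computes M-bias quality-control profiles with suggested trim bounds,
    marks PCR duplicates using both position and methylation identity, and
    simulates bisulfite reads with ground truth for accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    S4Vectors,
    grDevices,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
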