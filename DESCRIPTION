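Package: proteosig
Title: N-Terminal Extension Screening and Genome Membrane Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens proteomes for proteins carrying unique N-terminal
    extensions (NTEs) relative to their homologs, using filtered homolog
    hits from BLAST tabular files or a built-in affine-gap protein
    aligner, with cross-genome conservation analysis, detection of
    conventional/NTE paralog pairs, and Eisenberg hydrophobic-moment
    scoring of extensions for amphipathic-helix character. Also places
    genomes in a two-dimensional membrane-signature space (fraction of
    transmembrane proteins versus the ratio of Sec signal-peptide calls
    under two predictor regimes), fits bivariate-normal confidence
    ellipses to reference panels, and flags structural outliers by
    Mahalanobis distance. Includes rule-based transmembrane and
    signal-peptide predictors, parsers for TMHMM-style and signal-peptide
    summary outputs, and seeded simulators that generate homolog families,
    proteomes and reference panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
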