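Package: phagenomics
Title: Comparative Genomics, Gene-Sharing Networks, Virome Fragment
    Recruitment, and Prophage Integration-Site Detection for Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing novel bacteriophage genomes:
    shared-gene comparative genomics at configurable homolog thresholds, a
    gene-content network built from Markov-clustered protein families and
    hypergeometric genome similarity, reciprocal best-hit recruitment of
    viromic reads with group-level RPKM normalization, and detection of
    prophage integration sites (attL/attR core sequences) from phage-host
    hybrid reads.  Includes a self-contained protein homology engine
    (affine-gap Smith-Waterman, Karlin-Altschul bit scores and E-values,
    six-frame translated search) and a synthetic-data generator producing
    annotated phage genomes, diverged genome families, truth-labeled
    viromes, and planted lysogens, so that every stage of the pipeline is
    testable end to end without external data or search binaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
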