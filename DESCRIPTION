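Package: aimsarch
Title: Bacterial Chromosome Architecture and AIMS-Constrained Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the replication-associated architecture of
    circular bacterial chromosomes. Infers replication origin and terminus
    positions from frame-specific pentamer composition of protein-coding
    genes, discovers Architecture IMparting Sequences (AIMS, strand-biased
    degenerate octamers whose abundance and leading-strand bias increase
    toward the replication terminus) with a segment-shuffled null
    calibration, detects arm-restricted inversions between closely related
    genome pairs from signed ortholog orders, quantifies the
    permissive-orientation bias of AIMS within horizontally acquired
    insertions and the implied terminus-region loss of foreign DNA, scores
    donor genomes for AIMS compatibility with a recipient, simulates
    inversion counter-selection by polar Ter-like sites, and provides
    codon-usage, inverted-repeat, operon-length and synonymous-divergence
    confound controls. A synthetic-genome generator with planted ground
    truth exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
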