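Package: nanotax
Title: Real-Time Taxonomic Classification of Nanopore Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a real-time nanopore
    metagenomic identification pipeline: per-molecule read selection from
    grouped 2D/1D basecalls, batched streaming of FASTQ files from a run
    directory, a from-scratch seed-and-extend nucleotide aligner with
    Karlin-Altschul e-value statistics, cascaded host subtraction and
    tiered reference classification with lowest-common-ancestor
    resolution, completeness-prioritized reference selection, live count
    reporting, and reference-directed pileup consensus with banded
    pairwise identity. Includes a nanopore-like read simulator
    (substitution/insertion/deletion error model, log-normal read
    lengths) so the whole pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
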