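Package: dupdepth
Title: Read-Depth Copy Number for Highly Duplicated Genomic Domain Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures copy number of highly duplicated genomic domain families
    (such as DUF1220/Olduvai domains in the NBPF genes) from whole genome
    sequencing read depth. Provides a truth-tagged paired-end read simulator
    with empirical quality and error models, an exhaustive small-reference
    oracle mapper implementing four alignment strategies (best, best-with-ties
    multiread correction, and align-all variants), multiread-corrected
    fragment coverage with background and GC-bias normalization, read-ambiguity
    matrices and ambiguity-driven gene grouping, copy-number aggregation at
    domain, gene-clade, group-clade, clade and gene levels, and an RMSE /
    off-target evaluation framework for selecting sequencing and alignment
    parameters. A synthetic-genome fixture generator makes the full pipeline
    testable without a human reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    optparse
Config/testthat/edition: 3
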