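Package: mulmap
Title: Minimum Unique Length Mappability for Genomes, Bisulfite Genomes
    and Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes, stores and queries per-position minimum unique
    length (MUL) mappability tracks: for every genomic coordinate, the
    shortest read starting there that aligns to exactly one location.
    Supports plain genomes, bisulfite-converted genomes (per-strand
    C-to-T and G-to-A references), and spliced transcriptomes with
    gene-level and transcript-level uniqueness. Includes Gaussian
    fragment simulation for paired-end effective-length estimation,
    MUL-corrected RPKM expression quantification from uniquely mapped
    alignments, a compact binary track format with a text sidecar, and
    a seeded synthetic-data generator for genomes, annotations and
    read alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
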