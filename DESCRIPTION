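Package: capscaffold
Title: Cap-Adapted Full-Length RNA Scaffolds from Nanopore Direct RNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies 5'-cap-adapted direct-RNA nanopore reads by semi-global
    alignment of a cap-adapter barcode, filters them through a strand-aware
    cascade (quality gate, adapter true-positive cross-check, 5' clip filter,
    poly(A) tail and poly(A)-site window filters) into high-confidence
    full-length poly(A) RNA isoform scaffolds, discovers novel transcription
    start sites by single-linkage clustering of read 5' ends, and validates
    candidate starts with orthogonal marker overlap and a 5' RACE ratio
    statistic. Ships a deterministic seeded simulator of toy genomes,
    annotations and adapter-bearing read sets with planted truth so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
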