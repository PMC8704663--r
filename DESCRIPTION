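Package: teicaller
Title: Reference-Guided Detection of Transposable Element Insertions
    from Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transposable element insertions (TEIs) and
    TE-containing structural variants from low-coverage long-read
    (Oxford Nanopore scale) alignments to a reference genome. Scans
    CIGAR strings for large soft/hard clips and in-read insertions,
    merges adjacent reference breakpoints into candidate loci, re-maps
    the unaligned segment sequences to the genome, assigns the best
    matching annotated TE to each locus, and removes candidates whose
    local coverage is an outlier against an empirically sampled
    genome-coverage distribution. Includes downstream utilities
    (assembly-gap discovery, control-call subtraction, between-sample
    comparison, per-TE tallies) and a synthetic mobilome simulator that
    plants TE insertions with target-site duplications and emits reads
    with analytically computed alignments, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
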