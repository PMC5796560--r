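Package: teclust
Title: Mobile Element Insertion Calling from Targeted Paired-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects active transposable element insertions (L1HS, AluYa5/8,
    AluYb8/9) from targeted paired-end sequencing libraries in which read 2
    starts at a subfamily-diagnostic nested primer and read 1 anchors the
    unique 3' genomic flank. Provides read-pair filtering on primer and
    TE-like sequence evidence, positional clustering of read-1 anchors,
    annotation against reference repeat tracks and polymorphic-insertion
    databases, truth-set evaluation (including trio inheritance and long-read
    validation), primer-site genomics on a reference sequence, and a
    synthetic-library simulator with planted ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    methods,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    withr
Config/testthat/edition: 3
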