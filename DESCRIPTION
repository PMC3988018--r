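Package: cmtseq
Title: Constrained Multi-Level Thresholding Peak Calling for ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects enriched regions (peaks) in ChIP-Seq data by constrained
    multi-level thresholding (CMT). Aligned reads in BED format are extended
    to fragments and piled into per-chromosome nucleotide-resolution coverage
    histograms; division points between neighbouring peaks are placed by
    maximizing the positional between-class (Otsu) variance within windows
    bounded by user-specified minimum and maximum region sizes. Candidate
    regions are shrunk to their supported footprint and filtered against a
    control sample by a k-fold squared-density criterion, then ranked by fold
    enrichment. The package also implements the surrounding evaluation
    machinery (swap-based false discovery rate, IUPAC motif enrichment
    scoring against length-matched random intervals, summit-based overlap
    between peak sets, genomic-feature assignment) and a seeded synthetic
    read/genome simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'histogram.R'
    'cmt.R'
    'refinement.R'
    'evaluation.R'
    'simulate.R'
    'pipeline.R'
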