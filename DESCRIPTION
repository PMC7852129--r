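Package: misasm
Title: Read-Depth Auditing of Collapsed Duplications in Short-Read Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises misassembled regions of short-read
    genome assemblies from read-depth signal. Calls high-, low- and
    background-coverage regions from per-bin normalized read depth with GC
    correction and a dual q-value/read-depth thresholding scheme, classifies
    assembly regions into six correctness/duplication categories (C1-C3,
    M1-M3) from whole-genome alignment blocks against a reference (truth)
    assembly, extracts per-region and flanking-window genomic features
    (feature-track densities, GC, k-mer and simple-sequence-repeat
    composition, functional-annotation presence), trains balanced
    random-forest region classifiers, and provides enrichment and
    randomization statistics (log-likelihood ratios, Fisher tests,
    reshuffling and matched-random-region z-scores). A bundled
    synthetic-genome generator plants duplications, collapse events, gaps and
    annotation tracks and simulates binned read placements, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    ranger,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
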