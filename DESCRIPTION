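Package: rjmap
Title: Repeat Junction Marker Design and Deletion Bin Mapping by Comparative Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of genome-specific oligonucleotide markers from transposable-element
    insertion sites (repeat junction / ISBP markers) and genes, and their physical mapping
    to wheat-style chromosome deletion bins by two-channel comparative genomic
    hybridization against aneuploid stocks. Covers junction discovery in shotgun reads
    against a repeat library, a four-step 52-mer probe filter cascade (homopolymer runs,
    deep-read validation, copy-number screening, GC/Tm windows), quantile normalization and
    replicate-aware signal-loss testing with a decreasing stringency ladder, assignment of
    probes to chromosomes (nullisomic-tetrasomic panel) and to fraction-length deletion
    bins, and bin-map bookkeeping (bin physical sizes, pericentromeric subtraction, marker
    densities, genetic-map-based within-bin ordering). A synthetic-data module simulates
    repeat libraries, genomes with nested insertions, aneuploid line panels, error-prone
    shotgun reads and replicated hybridization signals with known ground truth, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
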