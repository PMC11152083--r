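Package: deltasnp
Title: Windowed Delta-SNP Divergence Scans, Genic Enrichment, and
    Inversion Detection from Whole-Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative divergence scanning across a small set of aligned
    genomes. Accumulates per-window SNP and aligned-base counts from
    multiple-alignment (MAF) blocks, standardizes per-window SNP proportions
    within chromosome classes, contrasts focal-species comparisons against
    control comparisons with the delta-SNP statistic, and selects
    top-quantile outlier windows intersected across focal comparisons.
    Companion analyses include a permutation test for genic enrichment of
    selected windows, a start-codon proximity rule for candidate gene
    nomination, strand-run inversion detection from pairwise alignment (PAF)
    records, neighbor-joining guide trees from alignment-derived distances,
    assembly summary statistics, and a four-species Jukes-Cantor alignment
    simulator with planted divergent windows and inversions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
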