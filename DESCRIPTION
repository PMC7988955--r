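Package: bactometh
Title: Bacterial Methylome Profiling from Per-Site Base-Modification Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis of single-molecule base-modification calls
    on closed bacterial chromosomes. Enumerates methylation-context sites
    (Dam GATC, Dcm CCWGG, CpG, CHG, CHH) on both strands of a circular
    genome, computes per-context methylation percentages with coverage
    filtering, builds binned genome-wide methylation profiles, TSS/TTS
    anchored gene metaplots with k-means clustering of promoter
    methylation, profiles CRISPR array spacer/repeat methylation
    periodicity and self-targeting spacers, summarises strand-resolved
    gene distribution and GC skew, and discovers enriched methylated-base
    motifs de novo by k-mer enrichment. Ships a seeded synthetic-data
    generator (genomes, annotations, CRISPR arrays, per-site methylation
    tables) so every stage is testable without raw signal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
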