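Package: bsascan
Title: Bulked-Segregant Analysis by Sequencing with Pooled Allele-Frequency Index Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci from pooled
    whole-genome resequencing of phenotypically extreme bulks (BSA-seq /
    QTL-seq). Computes per-site SNP/InDel indices (pooled alternate-allele
    frequencies) and their difference between high and low bulks, applies
    the standard read-depth and index filters, aggregates the delta index
    over sliding genomic windows with simulated binomial confidence
    intervals, and calls candidate regions supported consistently by the
    SNP and InDel tracks. Also provides codon-aware variant consequence
    classification against gene models, candidate-gene prioritisation by
    effect severity, hypergeometric GO term over-representation tests,
    haplotype-phenotype comparison across environments, and a seeded
    synthetic-data generator that emulates an extreme-pool experiment on a
    natural population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tibble,
    tidyr,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
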