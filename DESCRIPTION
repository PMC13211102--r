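Package: bsaqtl
Title: Bulk Segregant Analysis of Quantitative Traits from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for QTL mapping by bulk segregant analysis
    sequencing (BSA-seq) in biparental populations. Provides a forward
    simulator of F2 bulk-segregant experiments (Mendelian segregation with
    Haldane recombination, truncation-selected extreme bulks, negative
    binomial read sampling) with companion gene-model, differential
    expression and metabolite tables; GATK-style hard filtering and
    informative-site selection of multi-sample variant calls; per-site
    SNP-index, delta-index and Euclidean distance association statistics
    with sliding-window smoothing; significance thresholds by simulation
    based confidence intervals (delta-index) and the genome-wide
    median + 3 SD rule (ED); candidate-region calling and interval-algebra
    combination across methods and variant types; gene overlap, codon-level
    variant effect classification, hypergeometric enrichment; and
    integration with differential-expression contrasts and hormone
    fold-change calls into a ranked candidate-gene report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    rtracklayer,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
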