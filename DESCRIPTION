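Package: myoseq
Title: Consensus Differential Expression Analysis for Myometrial Bulk RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, tested implementation of a tri-method consensus
    workflow for bulk RNA-seq of human myometrium sampled at different stages
    of term labour. Builds flattened gene models from GFF/GTF annotation with
    exclusion of retained-intron transcripts, counts uniquely mapped fragments
    under a strict exon-overlap rule, computes TPM, calls differentially
    expressed genes by consensus of three negative-binomial testers (exact
    conditional, Wald GLM and empirical-Bayes model posterior), applies a
    median-TPM-floored fold-change filter, partitions gene lists across
    contrasts sharing a reference group, and performs GO over-representation
    with an expression-based custom background. A companion qPCR module covers
    standard-curve quantification, dual-housekeeper geometric-mean
    normalization, Welch-type and exact rank-based tests, and in-silico PCR.
    Seeded synthetic-data generators with known ground truth make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
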