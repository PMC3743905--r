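Package: lncforge
Title: Identification and Characterization of Long Non-Coding RNAs from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-assembly pipeline for identifying putative long non-coding
    RNAs (lncRNAs) from assembled transcript models. Implements a staged filter
    cascade (length, single-exon support, expression noise threshold derived
    from the read mapping rate, assembler class codes, coding potential, and
    coding-gene proximity) with a per-stage audit, genomic classification into
    intergenic, intronic, cis-antisense and alternatively spliced categories,
    multi-omic characterization against EST, repeat, ribosome-footprint, CAGE,
    conservation and chromatin-mark tracks, exclusion-aware genomic permutation
    tests with empirical p-values, construction of gene lists for functional
    enrichment, and percentile-threshold calling of expression changes in an
    RNAi knockdown microarray screen. A synthetic-fixture generator with a
    ground-truth manifest supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
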