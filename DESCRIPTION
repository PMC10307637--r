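Package: enhancerscope
Title: Enhancer Classification, Super-Enhancer Detection and Motif-Mutation
    Association from Differential Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for regulatory-genomics analysis of transcription
    factor knockout experiments. Classifies putative enhancers into direct
    and indirect, activated and repressed classes by combining transcription
    factor binding with a negative-binomial differential test on H3K27ac
    ChIP-seq signal; detects super-enhancers by signal stitching with a
    rank-signal elbow cutoff; defines cell-type signature genes and tests
    gene-set overlaps with one-tailed hypergeometric enrichment; scores
    position weight matrices for motif scanning, GC-matched motif
    enrichment, cross-species conserved-motif mapping, and a signed-rank
    association test between motif mutations and strain-differential
    binding. Includes seeded synthetic-data generators with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
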