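Package: ssrscape
Title: Microsatellite Landscape, Population Diversity and Transcriptogram
    Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing the microsatellite (SSR) landscape of a
    draft plant genome and relating it to population diversity and drought
    transcriptomics. Provides a MISA-style perfect tandem-repeat scanner with
    canonical motif classes, locus merging and transcribed-SSR flagging;
    chi-square bias tests on class composition; exclusive/equal/preferential
    classification of SSR allele diversity between two populations;
    negative-binomial maximum likelihood and two-group likelihood-ratio tests
    for differential expression with median-of-ratios normalization and
    Benjamini-Hochberg adjustment; transcriptogram profiling (gene ordering on
    a scored association network by simulated annealing, sliding-window
    expression averages, peak calling and GO density tracks); linking of SSR
    loci to nearby genes and presence/absence expression tests; and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    MASS,
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
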