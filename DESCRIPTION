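Package: epiregpair
Title: Matched-Pair Epigenome and Transcription-Factor Network Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for integrative epigenome/transcriptome
    analysis of individually matched case-control pairs: consensus-peak
    differential binding with TMM normalization and principal-component
    guided covariate regression, negative-binomial differential testing,
    enhancer-promoter annotation with chromatin-loop linking, per-sample
    transcription-factor regulatory networks ranked by personalized
    PageRank, antipsychotic-free versus antipsychotic-treated reversal
    classification, genome-binned chromatin-signal clustering with
    hypergeometric enrichment, age-correlation of pairwise differences,
    and ENCODE-style ChIP-seq quality metrics. Ships a synthetic-study
    generator with planted ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    igraph
Config/testthat/edition: 3
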