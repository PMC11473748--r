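Package: guardABA
Title: Guard-Cell ABA Response Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-course transcriptome studies of the
    abscisic acid (ABA) response in Brassica napus guard cells. Implements
    negative-binomial generalized linear model differential expression over a
    0/15/60-minute design with replicate batch effects (median-of-ratios size
    factors, profile-likelihood dispersion estimation with a parametric trend
    and empirical-Bayes shrinkage, Wald tests, Benjamini-Hochberg adjustment
    with independent filtering), temporal response classification, ortholog
    gene-family fold-change divergence statistics, gene-set enrichment with
    hypergeometric tests and Cramer's V effect sizes, signed regulatory-network
    direction-consistency odds ratios stratified by source-study size, promoter
    IUPAC binding-site scanning and enrichment, and a family-fixed-effects
    regression linking binding-site counts to fold change. A synthetic-study
    generator with recorded ground truth supports parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
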