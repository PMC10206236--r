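Package: strataprog
Title: Mixture-Model Patient Stratification Screens and Fixed-Width
    Enhancer Peak Analysis
Version: 0.1.0
Authors@R:
    person("Strataprog", "Developers", email = "strataprog@example.org",
           role = c("aut", "cre"))
Description: Tools for two complementary analyses of tumor cohorts and
    knockdown experiments. The cohort arm fits per-gene univariate Gaussian
    mixtures (unequal variances, BIC model selection) to log2(FPKM+1)
    expression, stratifies patients into expression groups, and screens for
    genes whose groups differ in overall survival via Kaplan-Meier
    estimation and the multi-group log-rank test. The epigenome arm builds
    reproducible fixed-width (501 bp) H3K27ac consensus peak sets by
    summit standardization, blacklist filtering, score-per-million
    normalization and iterative overlap removal; counts fragments per peak;
    computes TMM factors, log-CPM, and a documented stand-in differential
    test with the field's FDR/log2FC call thresholds; scores transcription
    factor motif deviations (z-scores) against GC- and
    accessibility-matched background peaks; and links differential peaks to
    differential genes through GREAT-style basal-plus-extension regulatory
    domains. A synthetic-data module generates every input with known
    ground truth so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    limma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
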