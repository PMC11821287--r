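Package: ednaclock
Title: Epigenetic Age Clocks from Environmental DNA Methylation Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for fitting epigenetic age clocks from
    nanopore methylation summaries of environmental DNA (eDNA). Reads
    bedMethyl summaries produced per modification-calling submodel,
    reconciles 5mC/5hmC/other-modC/6mA calls across submodels, detects
    differentially methylated "aging" sites across sampled ages, annotates
    sites against a mitogenome feature map parsed from a GenBank flat file,
    and fits grouped penalized-regression clocks (ridge to group lasso via a
    mixing parameter) over a systematic grid of penalty mixes, fold
    assignments and site-grouping schemes, selecting the best clock by a
    dual standardized median-absolute-error criterion. Includes CIGAR-based
    read accuracy and identity QC and a synthetic-data generator that
    emulates the methylation structure of larval eDNA samples for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
NeedsCompilation: yes
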