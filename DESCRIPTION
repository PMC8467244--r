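Package: itacscreen
Title: Transcriptome and Methylome Screening Toolkit for Wood-Dust-Associated
    Sinonasal Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("ITAC", "Screening Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Integrative analysis pipeline for nasal intestinal-type
    adenocarcinoma (ITAC) screening data: LOWESS normalization of expression
    intensities against a cohort median reference, restarted k-means gene
    profile clustering under correlation distance with per-cluster group
    testing, a centroid-correlation diagnostic predictor with an abstention
    band, a beta-value EWAS with hemimethylation state calling and smoothed
    P-values over genomic probe order, cross-dataset sign-concordance
    replication, and a synthetic-data generator with planted truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
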