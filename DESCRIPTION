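Package: gscatac
Title: Chromatin-Accessibility Stratification of Glioblastoma Stem-Cell Cultures
Version: 0.1.0
Authors@R: person("HGCC", "Analysis", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for stratifying glioblastoma stem-cell (GSC)
    cultures by bulk ATAC-seq chromatin accessibility and for mapping mouse
    epigenome programs onto human cohorts. Provides peak-call merging and CPM
    normalisation, saturation-curve non-linear modelling of cumulative peak
    discovery, non-smooth NMF consensus clustering with cophenetic model
    selection, negative-binomial differential accessibility with
    cluster-unique peak filters, correlation-based peak-to-gene linkage with
    an empirical null, chromVAR-style transcription-factor motif deviation
    scoring, and a homolog-mediated mouse-to-human peak conversion procedure
    with random-peak null controls. A synthetic-cohort generator with planted
    cluster structure, peak-gene links and motif programs makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    IRanges,
    GenomicRanges,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    mclust,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
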