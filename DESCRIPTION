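Package: dbregions
Title: Differential Binding Regions from ChIP-seq with Region-Level Error Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo detection of differentially bound (DB) regions from
    ChIP-seq read data with correct control of error rates. Provides a
    simplified Poisson peak caller with seven peak-set consolidation
    strategies (per-library and pooled-library calling with union,
    intersection and two-sample variants), sliding-window read counting
    with directional fragment extension, negative-binomial quasi-likelihood
    testing via edgeR, and a hybrid procedure that combines window
    P-values within peak clusters using Simes' method so that the
    Benjamini-Hochberg procedure controls the false discovery rate across
    genomic regions rather than windows. Includes a two-group ChIP-seq
    read simulator (transcription-factor and histone-mark modes, balanced
    DB spike-ins, negative-binomial background blocks) and orchestration
    for simulation studies of type I error, FDR and detection power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    IRanges,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
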