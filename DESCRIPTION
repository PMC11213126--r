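Package: riboPause
Title: Differential Ribosome Pause-Site Detection and Quiescence Analyses for
    Aneuploid Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Codon-resolution analysis of ribosome-profiling data for
    comparing ribosome pausing between conditions, built around replicate-paired
    Fisher exact tests on per-codon footprint counts with Benjamini-Hochberg
    correction, gene-body occupancy normalization with pseudocounts, uncentered
    (cosine) correlation of occupancy traces, positional and amino-acid-context
    characterization of differential pause sites, spike-in-anchored per-cell
    normalization of bulk RNA-seq with a negative-binomial exact test, and
    TMM-normalized scoring of pooled barcode fitness screens. Includes
    synthetic-data generators with recorded ground truth (planted pauses and
    stall motifs, global transcriptome silencing against constant spike-ins,
    barcode pools evolving under per-gene fitness effects) for calibration and
    parameter-recovery testing of every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
biocViews: RiboSeq, Sequencing, GeneExpression, DifferentialExpression,
    Normalization, Software
RoxygenNote: 7.3.3
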