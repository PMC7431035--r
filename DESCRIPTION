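Package: crescreen
Title: Cross-Species Screening for Conserved Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects cis-regulatory elements (CREs) conserved between
    distantly related genomes by homolog-anchored local alignment.
    Implements affine-gap Smith-Waterman and Needleman-Wunsch alignment
    with Waterman-Eggert declumped suboptimal alignments, Karlin-Altschul
    E-value statistics (analytic ungapped lambda/K and empirical gapped
    calibration), a four-criterion conservation classifier (homolog
    linkage; identity/length/E-value thresholds; coding exclusion;
    repeat exclusion), reciprocal uniqueness verification, global
    refinement, and position-weight-matrix binding-site scanning with
    exact score-distribution p-values. A synthetic ortholog-locus
    generator plants conserved elements, exons, repeats and motifs with
    an exact truth set so recovery and specificity are measurable.
    Also provides startle-induced negative geotaxis (SING) performance
    scoring and the associated parametric/nonparametric statistical
    decision tree with a dual-control significance rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    nortest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
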