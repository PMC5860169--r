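Package: virotax
Title: Genome-Based Phylogeny and Classification of Prokaryotic Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome phylogeny and taxonomic classification of
    bacterial and archaeal viruses from intergenomic distances. Local
    alignments (high-scoring segment pairs) between genome pairs are
    produced by a built-in seed-and-extend aligner or imported from
    12-column tabular output of an external tool, corrected for
    paralogous matches with greedy trimming or coverage filtering, and
    converted to distances with the d0/d4/d6 genome-distance formulas.
    Pseudo-bootstrap resampling of the retained alignments yields
    replicate matrices and branch support for midpoint-rooted distance
    trees. Reference taxonomies are scored with a signed taxon-support
    statistic, distance thresholds are optimised by maximising a
    chance-corrected partition agreement index under linkage-fraction
    clustering, parameter settings are compared by two-step Pareto
    selection, and cluster host specificity is summarised with a
    Berger-Parker style index. A genome simulator with a known tree and
    taxonomy makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    IRanges,
    mclust,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
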