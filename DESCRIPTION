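Package: srnamir
Title: Small RNA miRNA Discovery, Differential Expression and Degradome
    Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete small-RNA sequencing analysis pipeline for plant
    miRNA studies: read cleaning and collapsing, non-coding RNA class
    annotation, conserved miRNA matching, novel miRNA discovery by hairpin
    precursor screening (MFE/AMFE/MFEI and processing-precision filters),
    exact-test differential expression between unreplicated libraries
    (Audic-Claverie), degradome-guided cleavage-site target calling with
    three-category classification, hypergeometric GO-term enrichment and
    Livak 2^-ddCt relative expression. Includes a synthetic-data generator
    that plants hairpin precursors, class-annotated background reads,
    differential abundances and degradome cleavage peaks with a
    machine-readable ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
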