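Package: axescreen
Title: Causal-Mutation Discovery Pipeline for Forward Genetic Screens
Version: 0.1.0
Authors@R: person("Genome", "Screens", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for identifying causal mutations in
    resequenced mutant strains from forward genetic screens in haploid
    microbes, modelled on the workflow that mapped axenic growth of
    Dictyostelium discoideum to loss of its NF1 (RasGAP) orthologue.
    Provides quality-threshold variant triage with common-variant
    subtraction, HGVS c.-notation parsing and coding-effect
    classification, read-depth duplication scanning by rolling-median
    smoothing, windowed Smith-Waterman homology profiling with global
    percent identity/similarity, membrane fluorescence patch
    quantification on outlined cells, and a synthetic-data generator
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
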