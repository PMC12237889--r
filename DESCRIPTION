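Package: microstab
Title: Assembly Processes, Co-Occurrence Network Stability and
    Environmental Thresholds for Depth-Stratified Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of depth-stratified microbial community
    surveys: alpha and beta diversity from taxon count tables, null-model
    partitioning of community assembly processes (beta nearest taxon index
    against a taxa-shuffle phylogenetic null, abundance-based Raup-Crick
    with Bray-Curtis), Spearman co-occurrence networks with topological
    summaries, per-sample cohesion (complexity) and robustness (stability)
    metrics, driver screening (Spearman, Mantel, linear models) and
    segmented-regression estimation of environmental tipping points.
    Includes a synthetic-data generator with known ground truth (trees,
    gradient-structured communities, piecewise responses) and a composed,
    fully seeded pipeline with provenance output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
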