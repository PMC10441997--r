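Package: microstab
Title: Co-Occurrence Network Stability Analysis for Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the stability of microbial communities from
    amplicon sequence variant (ASV) count tables. Builds signed co-occurrence
    networks from rank correlations, computes network topology, modularity and
    module hubs, null-model-corrected community cohesion, robustness under
    abundance-weighted extinction cascades, and vulnerability from global
    efficiency. Fits the Sloan neutral community model to occurrence
    frequencies, tests phylogenetic conservation of perturbation responses
    (consenTRAIT and Mantel correlograms), and measures Levins niche breadth
    and overlap. Includes seeded generators for synthetic communities (copula
    block-correlated tables, Hubbell neutral assembly, trees with
    clade-conserved traits) so every stage can be exercised without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    vegan,
    jsonlite,
    yaml,
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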