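Package: metatadr
Title: Hierarchical TAD Folding Analysis from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the hierarchical, tree-like organization of
    topologically associating domains (TADs) in Hi-C contact maps.  Builds
    higher-order domain ("metaTAD") trees by adjacency-constrained
    agglomerative clustering of TAD-TAD contacts, quantifies inter- and
    intra-domain contact enrichment against boundary-anchored placement
    nulls, relates tree topology to epigenomic feature tracks, compartments
    and lamina-associated domains, compares trees across differentiation
    time points (cophenetic correlation, local tree change, circular
    permutation overlap tests), and includes a lattice strings-and-binders
    polymer Monte Carlo model of hierarchical folding.  A synthetic-data
    generator with a planted TAD hierarchy makes every analysis stage
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp,
    ape,
    IRanges,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
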