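Package: netsubgraph
Title: Canonical Subgraph Census and Spectral Descriptors for Directed
    Molecular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes directed molecular networks (gene regulation,
    signal transduction) into canonical N-node subgraph patterns and
    characterizes each pattern with nine spectral graph energies
    (adjacency, Laplacian, signless Laplacian, and six generalized /
    asymmetric generalized energies), reciprocity, cyclomatic complexity,
    and a pluggable algorithmic-complexity estimate.  Provides exhaustive
    pattern catalogs for 2- to 5-node directed graphs, an ESU-style
    induced-subgraph census that reports node identities, minimal
    unique-identifier descriptor search, functional-subgraph containment
    and irreducibility analysis, Shannon entropy of subgraph frequency
    distributions, and odds-ratio enrichment of gene sets in subgraph
    modules.  Reads edge lists and minimal KEGG KGML; includes a
    synthetic-network generator with controllable reciprocity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
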