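Package: cismine
Title: Linear-Delay Enumeration of Connected Induced Subgraphs and
    Maximal Cohesive Subgraph Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reverse-search enumeration of all connected induced subgraphs
    of an undirected graph with linear delay and linear space, based on an
    anchor/utmost parent operation and a distance-array search state. On
    top of the enumerator, a miner reports all maximal cohesive subgraphs
    of a binary vertex-attributed graph (connected subgraphs whose vertices
    share at least S_min attribute dimensions), with anti-monotone pruning
    of covered sibling branches, a level-one special case, and a cutoff for
    children whose attribute signature equals their parent's. Includes
    edge-list and attribute-table readers, seeded random and
    planted-module generators, independent brute-force oracles for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
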