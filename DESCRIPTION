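Package: ivinet
Title: Composite Influence Scoring and Dense-Module Decomposition for
    Cross-Condition Key-Gene Nomination
Version: 0.1.0
Authors@R:
    person("Ivinet", "Developers", email = "ivinet@example.org",
           role = c("aut", "cre"))
Description: Tools for nominating key genes shared between two disease
    conditions from differential-expression evidence and an undirected
    gene-gene interaction network.  Implements multi-series DEG filtering
    and set-theoretic overlap, from-scratch graph centralities (degree,
    betweenness, neighborhood connectivity, H-index, local H-index,
    ClusterRank, collective influence) combined into spreading, hubness
    and Integrated Value of Influence (IVI) scores on a [1,100] scale,
    MCODE-style dense-module detection with recursive decomposition to
    triangle motifs, Hamiltonian-Energy profiling of the module
    hierarchy, and an end-to-end reproducible pipeline with a
    synthetic-data generator that plants known shared genes and dense
    modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
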