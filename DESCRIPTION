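Package: mixnet
Title: Randomization Tests and Simulations for Mixed-Species Grouping Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single- and mixed-species sighting clusters as weighted
    species co-occurrence networks. Provides margin-preserving randomization of
    binary occurrence matrices (checkerboard swaps, optionally stratified by
    habitat), Besag-Clifford sequential Monte Carlo p-values for global
    association, dyadic co-occurrence and node-strength statistics, permutation
    tests on conspecific group sizes, weighted betweenness ranks, a
    three-step cluster simulator separating abundance-driven from
    preference-driven network structure, and a ground-truth synthetic community
    generator for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
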