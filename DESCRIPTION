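Package: phynetclass
Title: Classification of Unrooted Phylogenetic Networks by Graph Reductions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding tree-basedness and related structural classes
    of unrooted phylogenetic networks. Implements the three reduction
    procedures that relate a network to simpler graphs (leaf cutting, leaf
    shrinking, leaf connecting), recognition of edge-based networks via their
    correspondence with generalized series-parallel (GSP) graphs with
    reduction-trace certificates, a constructive support-tree builder for
    edge-based networks, sufficient Hamiltonicity-based criteria for
    tree-basedness, toughness and chordality tests, exact brute-force oracles
    for tree-basedness and Hamiltonicity, synthetic network generators with
    ground-truth labels, and an exhaustive isomorphism-free enumerator of
    small proper phylogenetic networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: igraph, methods, jsonlite, ape, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
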