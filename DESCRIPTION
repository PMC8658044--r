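Package: ergged
Title: Graph Edit Distance Screening over Extended Reduced Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ligand-based virtual screening with the Graph Edit Distance
    (GED) over extended reduced graphs (ErGs). Molecules are attributed
    graphs whose nodes carry one of fifteen pharmacophore labels and whose
    edges carry a bond order; their dissimilarity is the minimum-cost edit
    script (node and edge insertions, deletions and substitutions)
    normalised by the summed node counts. The package provides the
    126-parameter edit-cost model with the Harper expert defaults, an exact
    branch-and-bound GED solver for small graphs, the fast bipartite
    (assignment-based) approximation, nearest-neighbour active/inactive
    classification, and an iterative algorithm that learns the full cost
    table by swapping the nearest same-class and different-class distances
    of one misclassified molecule per iteration. A seeded synthetic-data
    generator produces two-class ErG populations with known edit scripts
    for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
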