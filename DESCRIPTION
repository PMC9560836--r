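Package: benzentropy
Title: Degree-Based Graph Entropies for Benzenoid Line Graphs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes degree-based topological indices (Randic, atom-bond
    connectivity, geometric-arithmetic, and their neighbour-degree-sum
    variants ABC4 and GA5) and the associated Shannon-type graph entropies
    for line graphs of subdivision graphs of benzenoid systems.  Provides
    hexagonal-lattice generators for triangular benzenoids, hexagonal
    parallelograms, and the zigzag-edge coronoid fused with starphene,
    edge partitions by endpoint degree or neighbour degree sum in two
    strictly separated evaluation modes (published closed-form partition
    tables versus direct computation on the constructed graph), and a
    machine-readable discrepancy report comparing the two.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
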