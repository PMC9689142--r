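Package: sqwalk
Title: Missing-Link Prediction in Complex Networks via a Simplified Quantum Walk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores candidate missing links in undirected networks
    (protein-protein, metabolic, neural, social) with a simplified
    discrete-time quantum walk whose Hilbert space has dimension twice the
    number of nodes: a Grover-style coin built from adjacency and
    common-neighbour counts, a block shift operator combining per-node
    self-loops with a degree-normalised hop to the neighbourhood treated as
    a whole, and an observation functional weighted by the common-neighbour
    ratio. Fourteen classical similarity baselines (common-neighbour family,
    Katz, local path, commute-time, cosine on the Laplacian pseudoinverse,
    neighbour contribution) and a benchmark harness with random
    training/probe edge splits, sampled AUC and precision at top-L complete
    the toolkit, together with edge-list I/O and seeded synthetic network
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
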