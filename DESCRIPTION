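Package: bimaxent
Title: Maximum-Entropy Null Models for Degree Distributions of Bipartite
    Ecological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and tests the maximum-entropy (MaxEnt) null model for the
    degree distributions of bipartite ecological networks such as
    plant-pollinator, seed-dispersal and plant-herbivore webs. Solves the
    discrete MaxEnt distribution on a bounded support with a fixed mean,
    quantifies agreement between observed degree sequences and the null via a
    randomized likelihood-ratio (G) test and a Monte-Carlo-calibrated
    relative-width statistic (W95), reduces food webs to their basal-consumer
    bipartite subgraph, simulates heterogeneous systems built from
    MaxEnt sub-networks coupled through a shared super-generalist, and runs
    cross-network surveys with the associated contingency-table statistics.
    Includes a synthetic-network generator for testing every pipeline stage
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
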