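Package: polarnet
Title: Network Propagation for Prioritizing Macrophage Polarization Driver Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seed-based network propagation (random walk with restart over a
    symmetrically degree-normalized protein-protein interaction network) for
    prioritizing candidate regulators of the macrophage M1 to M2 transition.
    Curated M1/M2 driver genes are mapped to a prior vector, diffused over the
    interactome, and the top-ranked genes are extracted as an annotated
    subnetwork. Includes bench-quantification formulas (relative qPCR
    expression, tumor volume, enzymatic standard curves, arginase units), a
    synthetic-data generator (scale-free networks with a planted driver
    module and a two-group expression design), and a planted-module recovery
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
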