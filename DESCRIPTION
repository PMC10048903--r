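Package: bnhnet
Title: Bottleneck-Hub and Regulatory Motif Analysis of Molecular Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological characterisation of protein-protein interaction
    networks (degree distribution, clustering, neighbourhood connectivity,
    betweenness, closeness and eigenvector centrality, with log-log power-law
    fits), identification of hubs, bottlenecks and bottleneck-hubs, a
    from-scratch implementation of the MCODE dense-complex detection
    algorithm, crosstalk scoring between bottleneck-hubs and detected
    subnetworks, construction of signed TF-miRNA-gene regulatory networks
    with enumeration and classification of feed-forward and feedback loops,
    hypergeometric over-representation analysis, and seed-deterministic
    synthetic network generators for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
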