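Package: starval
Title: Local Sparseness Analysis of Attributed Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the communication load that a vertex carries for its
    immediate neighbourhood in directed and undirected networks via the star
    value, a normalized count of the non-adjacent spoke pairs a hub mediates.
    Extends the analysis to vertex-attributed networks (e.g. cortical
    super-areas of the macaque connectome) with attribute disparity of local
    subnetworks, a per-group workload closure coefficient, and the
    Gould-Fernandez brokerage census. Provides degree-preserving
    (Maslov-Sneppen), block-constrained, and isomorphic null models, seeded
    random-graph generators, and tidy per-vertex, per-group and per-network
    summary tables with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
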