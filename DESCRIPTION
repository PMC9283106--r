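Package: msnflex
Title: Multilayer Morphometric Similarity Networks and Nodal Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject signed morphometric similarity networks (MSNs)
    from regional cortical morphometry, thresholds them to a fixed density with
    an orthogonal maximum-spanning-tree cost function, stacks individuals as
    ordinally coupled layers of a multilayer network, optimizes multislice
    modularity with a generalized Louvain algorithm, and quantifies nodal
    flexibility, flexible/inflexible hubs, and group differences in flexibility
    with age and IQ via bootstrap ensembles and nonparametric tests. Ships a
    synthetic cohort generator with planted lobe-aligned block structure so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
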