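Package: vtatrace
Title: Quantitative Analysis of Monosynaptic Rabies Input Mapping to VTA Dopamine Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying brain-wide monosynaptic rabies-virus input
    maps to ventral tegmental area (VTA) dopamine neurons: input-fraction
    accounting over a 57-region catalog, convergence-index and per-10,000
    normalization, marker-conditional (GAD/TH/Tph2) input maps, ensemble UMAP
    embedding with max-normalized pairwise-distance aggregation and
    hierarchical clustering of region covariation profiles, and medial-lateral
    axon-innervation intensity profiles. Includes a synthetic cohort generator
    that emulates the statistical structure of such experiments so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    uwot,
    cluster,
    FNN,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
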