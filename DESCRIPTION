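Package: domnet
Title: Signed Weighted Molecular Correlation Networks for Dissolved
    Organic Matter Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds signed weighted correlation networks from direct-infusion
    high-resolution mass spectrometry (HR-MS) profiles of dissolved organic
    matter (DOM). Provides peak-list filtering (signal-to-noise, blank
    exclusion, acquisition window), exhaustive molecular-formula assignment
    from exact mass with chemical-plausibility rules, signed soft-threshold
    adjacency with scale-free topology diagnostics, hierarchical module
    detection with module eigengenes, classical multidimensional scaling of
    the network dissimilarity, KEGG-style pathway coverage statistics with
    per-formula intensity deduplication, convergence/divergence trend
    statistics across sample groups, and a module-by-pathway overlay. A
    synthetic-data generator emulating a multi-litter decomposition design
    with planted correlation blocks provides ground truth for every stage,
    and a deterministic end-to-end pipeline ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
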