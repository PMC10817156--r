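Package: phylocog
Title: Phylogenetic Profiling and Module Enrichment of Orthologous Group
    Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds clade-by-orthologous-group presence profiles around a
    seed group's functional association neighborhood, binarizes them at a
    within-clade presence threshold, weights present cells by association
    scores, biclusters the weighted matrix into rectangular modules with
    hierarchical clustering on both axes, scores every module for over- and
    under-representation with the hypergeometric distribution, and renders
    annotated heatmaps and tables. Includes validated readers and writers
    for flat association, membership, species and taxonomy-lineage files, a
    greedy identity clusterer for resolving seed groups from protein
    sequences, and a synthetic-data generator with planted module structure
    for offline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
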