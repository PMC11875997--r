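Package: embedcompare
Title: Class-Based Comparison of Labeled 2D Embedding Visualizations
Version: 0.1.0
Authors@R: person("Sam", "Fielding", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares two 2D embedding visualizations (e.g. UMAP or t-SNE
    scatter plots) that share class labels but have no point-to-point
    correspondence. Each embedding is partitioned, per class, into "core",
    "context", and "combined" regions on a distance-thresholded Delaunay
    neighborhood graph, and the regions are summarized into three class-level
    metrics: Confusion (intermixing within the core), Neighborhood
    (quantile-normalized boundary connectivity to other classes), and Size
    (centered log-ratio abundance within the combined region). Includes label
    hierarchy roll-up, a per-point k-nearest-neighbor Jaccard baseline for
    contrast, a seeded synthetic layout generator with plantable structural
    changes, metric-colored scatter rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    deldir,
    FNN,
    ggplot2,
    optparse,
    ragg,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    interp,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
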