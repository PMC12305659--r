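Package: cpbionet
Title: Bioactivity Networking of Cell Painting Profiles and Untargeted
    LC-MS Features
Version: 0.1.0
Authors@R:
    person("cpbionet", "developers", email = "cpbionet@example.org",
           role = c("aut", "cre"))
Description: Predicts bioactive metabolites in complex natural-product
    extracts by integrating image-based morphological profiles from the
    Cell Painting assay with untargeted LC-MS feature tables. Single-cell
    feature distributions are reduced to signed well-level scores against
    pooled vehicle controls (histogram-difference normalization), summarised
    into a per-sample phenotype-strength score, filtered against vehicle
    activity, reduced by fast correlation-based filtering (symmetrical
    uncertainty), and hierarchically clustered (Spearman distance, Ward
    linkage) with cluster gating driven by positive-control replicates.
    Per-MS-feature activity and cluster scores link phenotypes to chemistry
    in a thresholded bipartite sample-feature network with community
    detection, and candidate features are annotated by molecular formula,
    adduct and ppm mass accuracy. A synthetic-data module generates plates,
    feature tables and reference libraries with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    jsonlite,
    ape,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
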