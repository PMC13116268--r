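Package: stimplant
Title: Single-Cell Spatial Transcriptomics Analysis of Implanted Biomaterials
Version: 0.1.0
Authors@R:
    person("stimplant", "developers", email = "stimplant@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for imaging-based in-situ spatial
    transcriptomics (Xenium-style per-transcript coordinates, quality
    values and cell segmentation) applied to implanted biomaterials and
    the foreign body response. Provides dataset quality control,
    normalization, graph-based clustering and subclustering with explicit
    marker-gene filters, signed perpendicular distance of cells to an
    annotated scaffold surface with three-region (scaffold body, capsule,
    native skin) assignment, radius-neighborhood colocalization matrices
    between cell subpopulations, cluster-frequency statistics,
    over-representation analysis against user-supplied gene sets, a
    negative-binomial synthetic data generator with full ground truth,
    and a command-line pipeline chaining all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
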