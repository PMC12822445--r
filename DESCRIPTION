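Package: cpmp
Title: Agent-Attention Multiple Instance Learning for Continuous Recurrence Risk from Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Weakly supervised regression of a continuous MammaPrint-style
    recurrence-risk score from bags of whole-slide-image tile embeddings.
    Implements a spatially aware agent-attention transformer (linear in the
    number of tiles) with a class-token regression head, attention-rollout
    heatmaps with raster assembly and mask concordance, tile-phenotype
    subcluster analysis via Leiden clustering of class-token embeddings,
    typed intercellular graph statistics (MeanEdgeLength, tumor-cell
    density), and a seeded synthetic-cohort generator with planted spatial
    risk signal for end-to-end validation. Bags are read and written in an
    HDF5 layout; training uses Adam with linear learning-rate decay,
    gradient accumulation and early stopping under patient-level repeated
    five-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    rhdf5,
    deldir,
    igraph,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
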