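Package: gliaquant
Title: Quantification of Synaptic Amyloid-Beta and Glial Engulfment in 3D Confocal Stacks
Version: 0.9.0
Authors@R:
    person("Open", "Neuroimaging", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying amyloid-beta burden, synaptic colocalization and
    glial (microglial and astrocytic) engulfment of synapses in 4-channel 3D confocal
    image stacks. Provides per-channel segmentation, voxel-level percent-volume burden,
    pairwise and triple colocalization, conditional engulfment-enrichment ratios,
    plaque-paired region-of-interest study designs, linear mixed-effects inference with
    nested random effects and Tukey-adjusted post-hoc contrasts, and a synthetic
    fluorescence-microscopy generator with exact voxel-level ground truth so that every
    stage of the pipeline is testable without access to original tissue images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
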