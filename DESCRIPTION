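Package: projquant
Title: Quantification of Long-Range Axonal Projections from Single-Neuron Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assemble, measure and classify three-dimensional
    single-neuron reconstructions of cortical layer 2/3 pyramidal neurons.
    Reads and writes SWC morphology files, stitches per-section tracing
    fragments into complete reconstructions, computes dendritic and axonal
    morphometrics (cable length, stem counts, branch points), assigns axonal
    cable to named brain regions in a bregma-referenced coordinate frame,
    derives per-neuron projection profiles and thresholded projection-target
    matrices, classifies neurons by their dominant long-range target, and
    estimates axon-density hotspot centers across animals from voxelized
    density volumes. A synthetic-data generator produces reconstructions and
    multi-animal density volumes with known ground truth so that every
    pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
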