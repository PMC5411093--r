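Package: synapsequery
Title: Query-Based Probabilistic Synapse Detection for Multiplex
    Fluorescence Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised, query-based probabilistic detection of synapses in
    co-registered multi-channel immunofluorescence volumes such as array
    tomography stacks. A per-slice Gaussian background model converts raw
    intensities into per-voxel foreground probabilities; windowed probability
    products promote two-dimensional puncta; a slice-span attenuation factor
    favours puncta spanning multiple sections; and a grid search for
    presynaptic signal around every postsynaptic voxel combines the marker
    channels named by a user query into a per-voxel synapse probability map.
    Includes thresholding into connected-component detections, density-versus-
    threshold curves, precision/recall evaluation with Agresti-Coull intervals,
    and a planted-object scene simulator for end-to-end benchmarking without
    real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
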