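Package: shootseg
Title: Organ-Level Instance Segmentation of Single-Shoot Plant Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic instance segmentation of single plant-shoot 3D point
    clouds (maize and similar single-stemmed crops) into stem, leaf, tassel, ear
    and pot instances. Implements median-directed stem region growing with
    per-segment median-axis trimming, principal-axis shoot alignment, top-down
    coarse organ assignment under the entropic optimal-transport (Sinkhorn)
    distance, multi-label Markov random field refinement solved by
    alpha-expansion graph cuts, voxel simplification with k-nearest-neighbour
    label upsampling, organ-level accuracy metrics, and a deterministic
    synthetic shoot generator that provides ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
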