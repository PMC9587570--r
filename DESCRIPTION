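Package: angiotrace
Title: Unsupervised Vessel Segmentation and Diameter Tracking for
    Coronary Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments dark curvilinear vessels from grayscale coronary
    angiograms without training data and tracks vessel diameter along the
    traced path. The image is partitioned into fixed-size tiles, tiles are
    classified as vascular or nonvascular through a pluggable classifier,
    and a per-tile two-cluster intensity threshold is expanded into the
    eight neighbouring tiles by flood fill (regional parameter expansion).
    The binary mask is then traced with an optimal cover tree: directed
    chords ("covers") are cast across vessel cross-sections in five fixed
    directions, chained under angle- and length-continuity rules into
    spanning trees, and the longest-path tree is retained, pruning
    disconnected noise. Cover lengths yield a per-position diameter
    profile and a colour-coded overlay. A synthetic vascular phantom
    generator with exact ground truth supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    grDevices,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
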