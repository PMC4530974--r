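Package: octrima3d
Title: Near-Real-Time Intraretinal Layer Segmentation of Macular OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic delineation of eight intraretinal layer boundaries in
    macular spectral-domain optical coherence tomography (SD-OCT) volume data.
    Each boundary is detected as the minimum-weight path through an
    8-connected graph built on a directional gradient image, with inter-frame
    flattening and search-region refinement exploiting the spatial coherence
    of adjacent B-scans, biasing and masking to separate closely spaced
    boundaries, and enface-projection detection of vessel shadows for the
    retinal nerve fiber layer. Includes segmentation error metrics (signed,
    unsigned and 95th-percentile errors), plain-text interchange formats for
    volumes and surfaces, and a synthetic layered-phantom generator with
    speckle noise and vessel shadows so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    tiff,
    xml2,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
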