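Package: rheotrack
Title: Red Blood Cell Tracking and Cell-Free Layer Measurement in
    Microchannel Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic image analysis for in vitro blood flow experiments in
    microchannels. Detects and tracks individual red blood cells in
    fluorescence time-lapse sequences (median denoising, iterative intermeans
    thresholding, Sobel edge maps, connected-component properties, nearest-pair
    trajectory linking) and measures cell-free layer thickness in brightfield
    sequences via temporal extreme-intensity projection, binarization and
    wall-referenced per-column scanning. Also provides the classic ImageJ-style
    baselines (the six Z-projections, ROI tonality profiles, tolerance wand
    selection), trajectory statistics (mean squared displacement, radial
    dispersion), a ground-truthed synthetic scene generator for both imaging
    modes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
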