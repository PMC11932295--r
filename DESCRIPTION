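Package: cadmilume
Title: Quantification of Cadmium from Bioluminescence Color in Well-Plate Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for ratiometric bioluminescent
    cadmium assays photographed in a dark box. Detects luminescent wells in
    an RGB plate image by thresholding and connected-component shape
    filtering, extracts robust per-well color as background-subtracted
    channel medians, converts color to normalized chromatic coordinates and
    a green/red intensity ratio, fits a linear ratio-versus-concentration
    calibration from standard wells, and inverts it to estimate cadmium
    concentrations in unknown wells with classical inverse-prediction
    standard errors. Includes a seeded synthetic plate renderer with a known
    ground truth for every stage, unit conversions (concentration factor,
    millimolar to ppm), CSV/JSON reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    png,
    tiff,
    jpeg,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Visualization
RoxygenNote: 7.3.3
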