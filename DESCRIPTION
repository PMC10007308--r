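Package: thzleaf
Title: Dual-Modality Terahertz Imaging of Leaf Hydration
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for terahertz (THz) hydration
    mapping of plant leaves mounted on a metal backing. Implements a
    calibrated double-Debye optical model of liquid water, an effective-medium
    model of leaf tissue, and transfer-matrix reflectivity of the
    leaf-on-metal stack; a procedural drying-leaf phantom with vein/lamina
    water contrast and staged dehydration dynamics; a broadband time-domain
    spectroscopy (TDS) raster-scan simulator with frequency-resolved
    amplitude/phase imaging and penetration-depth mapping; a swept-frequency
    quantum-cascade-laser laser-feedback-interferometry (LFI) simulator with
    self-mixing amplitude recovery, thresholded hydration fractions and
    piecewise-linear dehydration staging; and system-metric and comparison
    reporting across the two modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
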