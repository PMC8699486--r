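Package: holosperm
Title: Stain-Free Sperm Inspection by Off-Axis Quantitative Phase Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for stain-free inspection of sperm cells
    trapped in self-assembled microdroplets and imaged by off-axis digital
    holographic microscopy. Forward-simulates off-axis interferograms of
    sperm-shaped phase phantoms on a hexagonal droplet-rug background,
    reconstructs quantitative optical path delay (OPD) maps by Fourier
    sideband demodulation and two-dimensional phase unwrapping, extracts
    per-cell morphological parameters (acrosome-head ratio, head radii
    ratio, midpiece-head ratio, vacuole and residual-cytoplasm content),
    applies morphological selection criteria for fertilization suitability,
    tracks cells to estimate velocities and motile fractions, and computes
    spatial and temporal interferometric noise statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    tibble,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
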