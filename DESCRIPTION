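Package: srsdepth
Title: Measurement Depth Analysis for Spatially Resolved Near-Infrared
    Tissue Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-tally Monte Carlo photon transport in layered turbid
    tissue with weighted absorption, Henyey-Greenstein scattering and
    annular surface detectors; spatially resolved spectroscopy (SRS)
    measurement-sensitivity maps and depth profiles from partial
    path-length differences between two detectors; peak-depth maps and
    regressions of measurement depth on the two source-detector
    distances; and the full SRS oximetry chain (spatial slope, absorption
    inversion by diffusion formula or Monte Carlo lookup table,
    two-wavelength hemoglobin concentrations and regional oxygen
    saturation), including an in-silico blood-layer phantom experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
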