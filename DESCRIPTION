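Package: dfonphot
Title: Single-Particle Two-Photon Photophysics of Dye-Based Fluorescent
    Organic Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward emission model and inference pipeline for dye-based
    fluorescent organic nanoparticles (dFONs) under pulsed two-photon
    excitation. Implements the rate-equation pulse-train emission model,
    the fluorescence saturation curve and its inversion to local-field
    corrected two-photon absorption cross sections (in
    Goeppert-Mayer units), the Lorentz local-field factor, and the
    quadratic photobleaching power law. Provides a scan-analysis stage
    (spot detection, 2D Gaussian point-spread-function fitting,
    power-squared brightness normalization, population statistics), a
    trace-analysis stage (saturation and monoexponential bleaching fits
    with Poisson weighting), and a seeded synthetic microscope-data
    generator with Poisson photon statistics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
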