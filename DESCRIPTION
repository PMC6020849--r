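Package: promscope
Title: Photonic Resonator Outcoupler Microscopy Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward electromagnetic modelling and image analysis for
    photonic-crystal (PC) biosensor microscopy of live-cell adhesion. Implements
    a rigorous coupled-wave analysis (RCWA) solver for one-dimensional grating
    stacks with trapezoidal sidewalls, a first-order perturbation and temporal
    coupled-mode surrogate for the resonance shift and scattering outcoupling
    caused by focal-adhesion-scale dielectric clusters (including a Mie
    scattering cross-section), per-pixel resonance fitting of hyperspectral
    reflectance cubes into peak-wavelength-shift (PWS) and peak-intensity-shift
    (PIS) images, cell morphometry (segmentation, boundary tracking, band
    kymographs, edge-versus-center statistics, cross-section profiles), and a
    synthetic scene generator that renders ground-truth cell scenes into noisy
    hyperspectral cubes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
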