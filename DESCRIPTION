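Package: cdrwaves
Title: Wavefront Dynamics of Circular Dorsal Ruffles from Time-Lapse
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of circular dorsal ruffles (CDRs) and
    similar actin waves in time-lapse phase-contrast microscopy, where
    wavefronts appear as intensity minima. Provides gradient-vector-flow
    active-contour tracking of closed wavefronts with cubic-profile
    sub-pixel relaxation, per-point normal velocity and curvature, the
    normalized-area velocity collapse with closed-form quartic
    extrapolation to zero area, linear and circular (periodic) kymographs,
    ROI minimum-intensity traces and recovery times, periodic
    spatiotemporal autocorrelation maps with Radon-transform velocity
    extraction, wave-event detection (initiations, annihilations,
    collisions with terminal gaps, spiral rotations), and a calibrated
    synthetic phantom generator with exported ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
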