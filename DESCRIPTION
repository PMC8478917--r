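Package: lamellikine
Title: Quantification of Cell Motility, Lamellipodial Dynamics, Actin Flow
    and FLIM-FRET Biosensor Activity
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested implementation of four quantification
    procedures for cell-migration imaging experiments: interval-based track
    speed and persistence statistics at the usable time interval (Mean Track
    Speed, Mean Track Persistence, mean-square displacement, directionality
    ratio over time, direction autocorrelation); leading-edge morphodynamics
    from segmented time-lapse movies (60-degree cone protrusion speed,
    protrusion stability, longest uninterrupted lamellipodium, curved-ROI
    centerline length and width); cross-correlation particle image
    velocimetry of F-actin retrograde flow with normalised-convolution
    interpolation and assembly-rate computation; and per-pixel
    Levenberg-Marquardt fitting of mono-exponential TCSPC decays mapped to
    FRET efficiency. A synthetic-data module generates correlated random
    walks, textured flow movies, protruding-sector mask movies and
    Poisson-noise TCSPC stacks with ground truth attached, so every stage is
    testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
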