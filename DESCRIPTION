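Package: plangait
Title: Planar Musculoskeletal Walking Simulation and Dynamic Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-dynamics simulation of human walking with a planar
    seven-segment skeleton driven by 18 Hill-type muscle-tendon units.
    Muscle stimulation profiles (onset, offset, amplitude per muscle, with a
    half-cycle left-right phase shift) are optimized with a covariance matrix
    adaptation evolution strategy to minimize a combined posture-tracking and
    metabolic-cost objective. Aging-related muscle degeneration is modeled as
    prolonged deactivation time, reduced maximum isometric force, and reduced
    maximum contraction velocity, applied singly or together. Stability of the
    resulting gait is quantified with the margin of stability (extrapolated
    center of mass relative to the base of support), step length, and
    center-of-mass velocity, and simulated joint kinematics are validated by
    cross-correlation against reference gait-cycle curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
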