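Package: forceclamp
Title: Calibration and Analysis of a Passive Electrostatic Force Clamp from
    Brownian Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for passive force clamping of
    charged nanoparticles in nanofluidic channels. Provides the closed-form
    clamp potential and its Boltzmann statistics, an overdamped Langevin
    (Euler-Maruyama) trajectory simulator with localization noise and
    per-particle charge heterogeneity, a binned drift estimator that maps
    force fields from Brownian trajectories, weighted nonlinear fitting of
    the clamp model with dimensionless pooling across particles,
    force-voltage linearity analysis, mean-squared-displacement analysis
    with thermalization times, and a synthetic interferometric-ring imaging
    stage with sub-pixel localization by radial symmetry of the outer rings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
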