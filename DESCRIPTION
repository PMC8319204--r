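Package: mfitrack
Title: Depth-from-Defocus 3D Reconstruction for Multifocal Microscopy
Version: 0.1.0
Authors@R:
    person("mfitrack", "developers", email = "mfitrack@example.org",
           role = c("aut", "cre"))
Description: Tools for calibrated three-dimensional reconstruction from
    four-plane multifocal dark-field microscopy recordings. Includes a
    Gaussian-beam optical forward model and synthetic-data generators
    (defocused beads, beating flagella, calibration grids, Brownian
    tracks), plane normalization and grid-based registration, interplane
    distance estimation, extended depth-of-field composites,
    intensity-weighted algebraic circle fitting for bead localization,
    radius-versus-z calibration with propagated z-precision, two-minima
    depth disambiguation across planes, nearest-neighbour track linking,
    localization-precision estimation from Brownian displacement
    statistics, flagellar centerline tracing with width- and
    intensity-based depth inference, beat kinematics (gyration-tensor
    nonplanarity, rolling velocity, Taubin osculating-circle curvature,
    Welch spectra, curvature harmonics, swim speed), and track-based 3D
    particle imaging velocimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    FNN
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
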