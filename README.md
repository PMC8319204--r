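# mfitrack

Calibrated 3D reconstruction for four-plane multifocal dark-field
microscopy, in R.

## The problem

Fast biological processes — beating sperm flagella, diffusing tracer
particles, the fluid flow they reveal — happen in 3D within milliseconds.
A multifocal adapter splits the light path of a single camera into four
images focused at different depths, acquired simultaneously at hundreds of
frames per second. The third dimension is then recovered by
**depth-from-defocus**: the blur of an object's image is compared with a
calibrated blur-versus-z relationship, giving sub-micrometer axial
localization across a ~21 µm depth and a large field of view.

`mfitrack` implements the complete computational chain:

* **Optical forward model / synthetic data** — Gaussian-beam PSF
  (`w(z) = w0 sqrt(1 + (z/z_R)^2)`, `z_R = pi w0^2 / lambda`), rendering of
  beads, flagella and calibration grids into four focal planes; Brownian
  (`D = k_B T / 6 pi eta R`) and flagellar-beat
  (`kappa(s,t) = C0 + C1 cos(2 pi f0 t - 2 pi s/lambda) + C2 cos(4 pi f0 t - 4 pi s/lambda)`)
  motion simulators.
* **Plane preparation** — blank-frame intensity normalization, grid-based
  plane registration (Li threshold, skeletonization, point-to-line ICP),
  interplane-distance estimation from sharpness maxima, extended
  depth-of-field composites with max-variance depth maps.
* **Bead 3D tracking** — LoG detection, the intensity²-weighted algebraic
  circle fit (`2 x xc + 2 y yc + b = x² + y²`, `R = sqrt(xc² + yc² + b)`),
  radius-vs-z calibration with propagated precision
  (`sigma_z = sigma_R / |dR/dz|`), two-minima depth disambiguation across
  planes, 1.5-µm nearest-neighbour track linking.
* **Brownian precision** — localization precision from displacement
  statistics, `sigma_P = sqrt(sigma_M² - 2 D dt)`.
* **Flagellum 3D** — centerline tracing, per-plane width/intensity
  profiles, calibrated width-map inversion, arc-length and temporal
  smoothing.
* **Beat kinematics** — gyration-tensor nonplanarity, rolling velocity,
  Taubin osculating-circle signed curvature, Welch spectra, curvature
  harmonics C0/C1/C2, robust-lowess swim speed.
* **Track-based PIV** — voxel-averaged 3D flow fields (4 × 4 × 2 µm
  voxels), glass-plane estimation, 2D projections.

## Worked example

Calibrate radius-vs-z on seven synthetic beads, then sweep an independent
validation bead through the depth range and regress inferred against true
z (runs in about a minute):

```r
library(mfitrack)
cfg <- optics_config(fov_px = 80)    # 20x/NA 0.5 + 1.6x, planes 0..8.8 um
psf <- gaussian_psf()                # w0 = 2.1 um at 530 nm
zs  <- seq(-10.5, 10.5, by = 0.2)   # piezo sweep
ctr <- (80 - 1) / 2

profile <- function(seed) {
  stack <- render_bead_zstack(zs, cfg, psf, seed = seed)
  t(sapply(stack, function(fr) measure_bead_radii(fr, ctr, ctr)$radius))
}
calib <- build_radius_calibration(lapply(1:7, function(i) profile(i * 100)), zs)

val   <- profile(9999)               # an unseen bead
z_hat <- sapply(seq_along(zs), function(i) {
  rr <- data.frame(plane = 1:4, radius = val[i, ], r2 = 1, valid = TRUE)
  infer_bead_z(rr, calib)$z
})
fit <- lm(z_hat ~ zs)
cat("slope:", round(coef(fit)[2], 3), "\n")
#> slope: 1.013
cat("residual sd (um):", round(sd(resid(fit)), 3), "\n")
#> residual sd (um): 0.41
cat("predicted mean sigma_z (um):",
    round(predict_z_precision(calib)$mean_sigma_z, 3), "\n")
#> predicted mean sigma_z (um): 0.339
```

The inferred depth tracks the piezo with unity slope across the full 21-µm
range, and the empirical scatter (0.41 µm) matches the precision predicted
by error propagation of the calibration curves (0.34 µm).
`predict_z_precision(calib)` gives the combined precision-versus-depth
curve; adding planes never worsens it.

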