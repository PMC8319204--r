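---
title: "Depth-from-defocus 3D reconstruction for multifocal microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mfitrack methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mfitrack)
```

# The measurement principle

A four-way image splitter projects four differently focused copies of the
sample onto one camera chip, so that a single exposure captures four focal
planes simultaneously — at 500 frames per second in the configurations this
package targets. An object's axial position is then inferred from how
defocused its image is in each plane ("depth-from-defocus"): beads blur
into wider, dimmer discs; flagella into wider, dimmer ribbons. Because the
blur-versus-z relationship is symmetric about each focal plane, a single
plane leaves a two-fold ambiguity (above or below focus); combining the
four planes resolves it and lets the most favorable plane set the
precision at every depth.

# The optical forward model

Defocus is modeled with a Gaussian-beam transverse profile
$I(r,z) \propto e^{-r^2/w(z)^2}$, whose width follows

$$ w(z) = w_0\sqrt{1 + (z/z_R)^2}, \qquad z_R = \pi w_0^2/\lambda . $$

* `w0` (µm) — in-focus width; **default 2.1 µm**. This is the resolution
  scale quoted for the reference hardware (20×/NA 0.5 objective, 1.6×
  changer, 530-nm LED, 11-µm pixels). Note that the stated resolution
  formula `abbe_limit()` = (n/NA)(λ/NA + e/M) evaluates to 2.8 µm with the
  same parameters; the two are not mutually consistent, so `w0` is kept as
  a free model parameter with the hardware-quoted default. At
  `w0 = 2.1 µm`, `z_R ≈ 26 µm`: defocus across the 21-µm working depth is
  *shallow*, which is the single most important property of this stated
  world — it caps every downstream precision (see "Numerical choices").
* `plane_offsets` — sample-space focal positions; default `0…8.8 µm` in
  equal steps (the span of the reference lens set f = ∞/1000/750/500 mm;
  `thin_lens_plane_offsets()` gives the ray-optics prediction from a relay
  geometry).
* Pixel pitch — 11 µm / 32 = **11/32 µm per pixel**, which also fixes the
  arc-length sampling pitch of flagellar analyses.

The renderer conserves energy: the paper-style amplitude factor
$w_0/w(z)$ does not conserve the integrated 2D intensity of a point source
(the integral grows linearly with $w$), so the renderer normalizes each
object's contribution to a constant total, making "defocus spreads but
does not destroy light" an exact property. Beads are rendered as
Gaussian-blurred discs (disc second moment `radius/2` added in
quadrature); filaments as a dense comb of Gaussian splats (one per pixel
pitch — far below the ≥4-px PSF width, so the comb is indistinguishable
from a continuous line); kernels are truncated at 4 standard deviations.

**Noise.** Dark-field contrast is bright-on-dark; the default noise model
is additive Gaussian read noise with sd = 2% of the frame's peak
noise-free intensity, optional Poisson shot noise, applied last under the
scene seed (bit-reproducible). For mixed scenes (bright head + dim
flagellum) the absolute `noise_sd` override ties the noise to the object
of interest instead of the head.

# Synthetic specimens: what they emulate, what they do not

* **Beads**: 500-nm latex spheres; Brownian motion from the
  Stokes–Einstein relation $D = k_BT/(6\pi\eta R)$ (at 295 K, 0.95 mPa s,
  250 nm: $D \approx 0.91\ \mu m^2/s$; per-axis step sd at 2 ms ≈ 0.060
  µm).
* **Flagella**: ~50-µm filaments driven by a traveling curvature wave
  $\kappa(s,t) = C_0 + C_1\cos(2\pi f_0 t - 2\pi s/\lambda_s) +
  C_2\cos(4\pi f_0 t - 4\pi s/\lambda_s)$ (defaults 0.02/0.05/0.006 µm⁻¹,
  25 Hz, λ_s = 25 µm — the human-sperm scale). The out-of-plane component
  is a traveling sinusoid whose amplitude ramps linearly from the head
  (default tip amplitude 1.5 µm); this is a fixture choice — real 3D
  waveforms are not parameterized by the generator. After adding it, the
  curve is rescaled about the head so every frame has exactly the nominal
  arc length (a raw additive z-displacement would stretch it by a few
  percent). A bright head bead (~5× the flagellar peak) emulates the
  strong head/flagellum contrast of dark-field sperm images and anchors
  the arc-length origin.
* **Not emulated**: optical aberrations, vectorial/high-NA PSF structure,
  scattering speckle, hydrodynamic coupling between specimens, motion blur
  within an exposure. A green test therefore establishes correctness of
  the *computational chain* under the stated optics, not robustness to
  every artifact of real recordings.

# Plane preparation

Intensity normalization divides each pixel by a smoothed fractional
intensity map from a blank recording. Registration segments a calibration
grid with Li's minimum-cross-entropy threshold, skeletonizes it
(Zhang–Suen), refines skeleton points to the intensity² ridge crest by a
mean-shift whose window is re-centered on the fractional estimate
(anchoring it at integer pixels pixel-locks the crest and quantizes the
recovered shift), and aligns planes to plane 1 with an ICP whose
similarity fit uses only the *normal* components of correspondences
(point-to-line): displacement along a grid line is unobservable, and
including it shrinks scale estimates by roughly half. The model is
translation + isotropic scale by default (rotation optional). Interplane
distances come from the piezo position maximizing each plane's intensity
standard deviation, refined by a parabola fitted across the top decile of
the sharpness curve — the peak is flat when `z_R` is large, and a 3-point
parabola is then quantization-limited. EDOF composites take each pixel
from the plane with the largest local variance (ties to the lowest index).

# Bead depth inference

Radii come from the intensity²-weighted algebraic circle fit on all pixels
within 10 px of the detection: rows $[2x, 2y, 1]$ scaled by $I^2$ against
$x^2+y^2$, radius $\sqrt{x_c^2+y_c^2+b}$; the fit quality $r^2$ is
computed on the weighted linearized residuals, and planes with
$r^2 \le 0.8$ are discarded (fewer than two valid planes excludes the
bead).

Calibration averages aligned per-bead radius profiles and smooths them
with a centered moving average of **2 µm** (not the 0.5 µm one might pick
by default): the physical curve varies on the Rayleigh-range scale
(tens of µm), while bead-noise wiggles at 0.1-µm steps corrupt both the
difference-function inversion and the derivative in
$\sigma_z = \sigma_R/|dR/dz|$; the derivative itself is a local-linear
(Savitzky–Golay) slope over the same window.

Per plane, the difference function $|R_{meas} - R_k(z)|$ is inverted on
the two monotone branches around the curve minimum (cumulative-max
envelopes, linear interpolation) — robust to residual calibration wiggles
where raw grid minima are not. Radii beyond a branch maximum extrapolate
with the branch-end slope and are flagged: clamping them to the grid
boundary creates artificial candidate clusters that can win the
combination search. The cross-plane combination of one candidate per plane
is selected by minimum *precision-weighted* dispersion, and the final z is
the precision-weighted mean of the winning members. This deviates
deliberately from selecting the single best-precision plane's member:
with shallow defocus, a plane measuring within its flat near-focus band
contributes a candidate that can sit micrometres from the truth while
formally looking precise, and single-member selection turns those into
gross outliers. The reported `sigma_z` remains the best plane's propagated
precision, matching `predict_z_precision()` (the pointwise minimum over
planes, which improves monotonically as planes are added).

With the full protocol (7 calibration beads, 0.1-µm steps, 2% noise) the
validation regression of inferred against true z has slope ≈ 1.00–1.01
and residual sd ≈ 0.4 µm versus a predicted mean precision of ≈ 0.33 µm.

# Brownian precision

Measured displacement distributions are the convolution of the
displacement-error distribution with the diffusion kernel, so variances
add: $\sigma_M^2 = \sigma_P^2 + 2D\Delta t$ and
$\sigma_P = \sqrt{\sigma_M^2 - 2D\Delta t}$. $\sigma_M^2$ is the
maximum-likelihood second moment of pooled displacements (no histogram
binning; a histogram + PDF-fit route is provided as a cross-check).
Note the convention: $\sigma_P$ is the *displacement* error sd.
Independent per-position localization errors of sd $s$ contribute $2s^2$
to $\sigma_M^2$, i.e. $\sigma_P = \sqrt{2}\,s$; the simulators in the test
suite inject per-position noise $s = \sigma_P/\sqrt 2$ so injected and
recovered values agree. Negative variance differences (finite-sample
undershoot) are reported as flagged zeros. Lag is one frame; drift can be
removed by per-track mean-displacement subtraction.

# Flagellum reconstruction

The sharpest plane (largest intensity sd) is traced: blur → Li threshold
→ skeletonize → longest path → smoothing spline → resample at 11/32 µm →
subpixel refinement of every point to the Gaussian center of its normal
profile → extension of both ends along the tangent to the half-plateau
intensity contour (thresholding erodes blurred ends by about one PSF
width; the line-spread function falls to half its plateau exactly at the
physical end). The head is the endpoint with the larger local integrated
intensity, and the arc origin is re-zeroed at the head's intensity
centroid — raw skeleton endpoints jitter by ~2 µm frame-to-frame, which
would alias into every arc-length-indexed quantity.

Widths come from a 1D Gaussian fit of the profile normal to the
centerline (±12 px, bilinear): an intensity²-weighted log-parabola —
exact for Gaussian ribbons on dark background and, unlike truncated
moments, fully sensitive to defocus — with the baseline re-estimated from
the fitted shape (an outer-sample median clips the tails when the window
is only ~2.5 sd wide and biases widths low by ~5%). Widths and peaks are
smoothed along the arc (2.2-µm median+mean window) before inversion.

The width calibration map $w(s, \Delta z)$ per plane averages immotile
cells swept through z and applies the 6 × 6 median filter; an even kernel
is phase-averaged so the map is not shifted by half a grid step. Width
inversion reuses the bead machinery (two candidates per plane, weighted
combination); per-cell spread propagates to a per-cell-map precision that
weights the combination. The intensity route fits a log-parabola to the
four (plane offset, peak intensity) points; with `z_R ≈ 26 µm` the
intensity varies only ~10% across the plane span, so this route is nearly
uninformative in the stated world and width is the default. z-profiles
are smoothed along s (2.2 µm median+mean, shrinking end windows) and, for
time series, lightly over time (3 frames; a 25-Hz beat at 500 fps loses
~3% amplitude).

# Beat kinematics

* **Nonplanarity**: gyration tensor of the centered point cloud; ratio of
  the two smallest eigenvalues (0 = planar, 1 = isotropic). The
  eigenvalue (not square-root) convention is used; a flag is trivial to
  add since the eigenvalues are returned.
* **Rolling**: signed rotation rate of the beat-plane normal about the
  head-to-tail axis (positive = clockwise viewed head-to-tail), averaged
  and reported in Hz (/2π). Normals are sign-aligned first (eigenvector
  signs are arbitrary).
* **Signed curvature**: per 4-µm arc window, project onto the window's
  two major gyration axes and fit Taubin's algebraic circle; κ = 1/R. The
  sign follows a binormal propagated continuously along s, with each
  frame's global sign aligned to the previous frame's binormal *field*
  (aligning only at the head produced isolated whole-frame flips).
* **Spectra**: Welch PSD with 200-sample Hann windows advanced by 40
  samples (series shorter than one window fall back to a flagged single
  periodogram); harmonics $C_0 = |\bar\kappa|$,
  $C_{1,2} = 2|X(f)|/N$ at $f_0$ and $2f_0$.
* **Swim speed**: robust locally weighted linear regression (tricube
  weights, bisquare robustification, 5 iterations) with an 8-ms window,
  then an 80-ms pass for the trajectory centreline; speed is consecutive
  centreline distance × frame rate.

# Track-based PIV

Instantaneous velocities of consecutive track points are assigned to the
4 × 4 × 2 µm voxel containing the displacement midpoint (unbiased for
linear fields) and averaged arithmetically; empty voxels stay absent,
never zero. The glass plane is the mean z of nonmoving beads, classified
by positional sd below 3× the expected Brownian step on every axis (a
diffusing bead wanders many steps over a track; a stuck one only by its
localization noise). 2D projections are count-weighted means across z.

# Known limitations

* The shallow defocus of the stated world (`w0 = 2.1 µm`) limits
  width-based flagellar z-precision to ~0.4–0.6 µm distally — comparable
  to the real-hardware figure, but achieved only with the widened
  calibration smoothing and precision-weighted combination described
  above. Near-focus bead depths carry the worst conditioning.
* Sign assignment of the 3D curvature is propagated from binormal
  continuity (per arc point over time, seeded along s in the first frame,
  confidence-gated at |κ| < 0.01 µm⁻¹). On reconstructions with ~0.4-µm
  z-noise it can still flip in blocks near the |κ| minima of a nonplanar
  beat; beat frequencies are therefore best read from coordinate
  kymographs, which lock to the fundamental regardless.
* Second-harmonic curvature amplitudes at the human-sperm scale
  (0.006 µm⁻¹) sit *below* the curvature noise floor of reconstructed
  coordinates (~0.01 µm⁻¹ after 6.6-µm pre-smoothing of z before
  curvature analysis): the full measurement chain can recover $f_0$ and
  $C_1$-scale structure, but $C_2$ at that magnitude is only testable on
  the clean generator chain. For a strongly nonplanar beat the signed 3D
  curvature never crosses zero, so its harmonic content differs
  intrinsically from the planar generating curvature — comparisons are
  made against the same metric applied to the true shapes.
* Track linking is greedy mutual-nearest-neighbour with a 1.5-µm radius:
  no gap closing, no global assignment.
* Registration assumes similarity transforms (no warps, no chromatic
  terms); the flagellum tracer assumes one dominant filament per field.
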