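#' Optical configuration of a four-plane multifocal setup
#'
#' Bundles the parameters of the microscope + multifocal-adapter combination
#' needed by the forward model and by the reconstruction code. The defaults
#' describe a dark-field setup with a 20x/NA 0.5 objective plus a 1.6x
#' magnification changer (total M = 32), a 530-nm LED, an 11-um camera pixel,
#' and four focal planes spanning 8.8 um in sample space.
#'
#' @param na numerical aperture of the objective (dimensionless, > 0).
#' @param n refractive index of the immersion/sample medium.
#' @param lambda wavelength in um.
#' @param e_pixel physical camera pixel size in um.
#' @param magnification total lateral magnification M.
#' @param plane_offsets length-4 numeric, sample-space focal position of each
#'   plane in um relative to plane 1; must be strictly monotonic.
#' @param fov_px integer length-2, per-plane field of view `c(nx, ny)` pixels.
#' @param lens_focal_lengths focal length (mm) of the relay lens in each of
#'   the four paths; `Inf` marks the lens-free path.
#'
#' @return An object of class `optics_config`.
#' @examples
#' cfg <- optics_config()
#' cfg$pixel_pitch   # sample-space um per pixel (e_pixel / M)
#' @export
optics_config <- function(na = 0.5, n = 1.0, lambda = 0.53,
                          e_pixel = 11, magnification = 32,
                          plane_offsets = seq(0, 8.8, length.out = 4),
                          fov_px = c(256L, 256L),
                          lens_focal_lengths = c(Inf, 1000, 750, 500)) {
  if (na <= 0 || lambda <= 0 || magnification <= 0 || e_pixel <= 0 || n <= 0)
    stop("invalid optics config: NA, n, lambda, e_pixel and M must be > 0")
  d <- diff(plane_offsets)
  if (length(plane_offsets) < 1 || any(!is.finite(plane_offsets)) ||
      (length(d) && !(all(d > 0) || all(d < 0))))
    stop("plane_offsets must be finite and strictly monotonic")
  if (length(fov_px) == 1) fov_px <- rep(fov_px, 2)
  structure(list(
    na = na, n = n, lambda = lambda, e_pixel = e_pixel,
    magnification = magnification,
    plane_offsets = as.numeric(plane_offsets),
    fov_px = as.integer(fov_px),
    lens_focal_lengths = lens_focal_lengths,
    pixel_pitch = e_pixel / magnification
  ), class = "optics_config")
}

#' Lateral resolution bound of the setup
#'
#' Resolution limit combining the diffraction term and the detector sampling
#' term: `r_z = (n/NA) * (lambda/NA + e_pixel/M)`.
#'
#' @param config an [optics_config()].
#' @return Length in um.
#' @examples
#' abbe_limit(optics_config(na = 0.5, lambda = 0.53, e_pixel = 11,
#'                          magnification = 32))  # 2.8075
#' @export
abbe_limit <- function(config) {
  stopifnot(inherits(config, "optics_config"))
  (config$n / config$na) *
    (config$lambda / config$na + config$e_pixel / config$magnification)
}

#' Gaussian-beam point-spread-function model
#'
#' A defocused point is modeled with the transverse profile
#' `I(r, z) ~ exp(-r^2 / w(z)^2)` where the width follows the Gaussian-beam
#' law `w(z) = w0 * sqrt(1 + (z/z_R)^2)` with Rayleigh range
#' `z_R = pi * w0^2 / lambda`. The in-focus width `w0` is a free parameter;
#' the default of 2.1 um corresponds to the resolution scale of the default
#' [optics_config()] hardware.
#'
#' @param w0 in-focus beam width in um.
#' @param lambda wavelength in um.
#' @return Object of class `gaussian_psf` with fields `w0`, `lambda`, `z_r`.
#' @export
gaussian_psf <- function(w0 = 2.1, lambda = 0.53) {
  if (w0 <= 0 || lambda <= 0) stop("w0 and lambda must be > 0")
  structure(list(w0 = w0, lambda = lambda, z_r = pi * w0^2 / lambda),
            class = "gaussian_psf")
}

#' Defocused beam width
#'
#' @param z_offset axial distance(s) from focus, um (vectorized).
#' @param model a [gaussian_psf()].
#' @return Width(s) `w(z)` in um; even in `z_offset`.
#' @export
psf_width <- function(z_offset, model) {
  stopifnot(inherits(model, "gaussian_psf"))
  model$w0 * sqrt(1 + (z_offset / model$z_r)^2)
}

#' Thin-lens prediction of the focal-plane offsets
#'
#' Predicts the sample-space focal offset of each relay path from sequential
#' thin-lens imaging (1/f = 1/s + 1/s'). Each path holds a lens of focal
#' length `f` at distance `d_lens_camera` (mm) before the camera chip. The
#' aerial image that the path brings into focus on the chip is displaced
#' axially by `d^2 / (d - f)` in image space relative to the lens-free path;
#' division by the axial magnification `M^2 / n` converts to sample space.
#'
#' @param config an [optics_config()] (uses `lens_focal_lengths`,
#'   `magnification`, `n`).
#' @param relay_geometry list with element `d_lens_camera` (mm), the distance
#'   from the inserted lens to the camera chip.
#' @return Numeric vector of sample-space offsets (um), lens-free path at 0.
#' @export
thin_lens_plane_offsets <- function(config, relay_geometry) {
  stopifnot(inherits(config, "optics_config"))
  d <- relay_geometry$d_lens_camera
  if (is.null(d) || d <= 0) stop("relay_geometry$d_lens_camera must be > 0")
  f <- config$lens_focal_lengths
  if (any(!is.infinite(f) & f <= 0)) stop("focal lengths must be positive or Inf")
  if (any(is.finite(f) & f == d))
    stop("singular geometry: image forms at infinity (f == d_lens_camera)")
  shift_mm <- ifelse(is.infinite(f), 0, d^2 / (d - f))
  ax_mag <- config$magnification^2 / config$n
  shift_um <- shift_mm * 1e3 / ax_mag
  shift_um - shift_um[1]
}
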