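#' Scene descriptions for the synthetic renderer
#'
#' A scene is a list of objects (beads, filaments, grids) plus a background
#' level and a noise model. Dark-field contrast is emulated: bright objects on
#' a dark background. All coordinates are in um; z = 0 is the focus of plane 1
#' and z increases away from the objective.
#'
#' @param objects list of objects built with [scene_bead()],
#'   [scene_filament()] or [scene_grid()].
#' @param background_level constant background (counts).
#' @param noise_sd_frac Gaussian read-noise standard deviation as a fraction
#'   of the peak noise-free object intensity in the frame (default 0.02).
#' @param noise_sd absolute Gaussian read-noise sd in counts; overrides
#'   `noise_sd_frac` when given (useful for mixed scenes where a bright head
#'   would otherwise set the noise scale).
#' @param poisson logical; also apply Poisson shot noise.
#' @param seed integer or NULL; RNG seed used when noise is applied. Rendering
#'   the same scene with the same seed is bit-reproducible.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(objects = list(), background_level = 0,
                       noise_sd_frac = 0.02, noise_sd = NULL,
                       poisson = FALSE, seed = NULL) {
  stopifnot(is.list(objects))
  for (ob in objects) {
    if (!inherits(ob, "scene_object")) stop("objects must be scene_* objects")
  }
  structure(list(objects = objects, background_level = background_level,
                 noise_sd_frac = noise_sd_frac, noise_sd = noise_sd,
                 poisson = poisson, seed = seed),
            class = "scene_spec")
}

#' @param center length-3 numeric (x, y, z) in um.
#' @param radius physical bead radius in um (default 0.25, a 500-nm bead).
#' @param brightness total integrated intensity (counts) of the bead image.
#' @rdname scene_spec
#' @export
scene_bead <- function(center, radius = 0.25, brightness = 5000) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            radius > 0, brightness >= 0)
  structure(list(kind = "bead", center = as.numeric(center),
                 radius = radius, brightness = brightness),
            class = c("scene_bead", "scene_object"))
}

#' @param points n x 3 matrix of polyline vertices (x, y, z) in um.
#' @param thickness filament thickness (Gaussian cross-section sd ~
#'   thickness/2) in um.
#' @param brightness_per_um integrated intensity per um of filament length.
#' @rdname scene_spec
#' @export
scene_filament <- function(points, thickness = 0.4, brightness_per_um = 3000) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2, all(is.finite(points)),
            thickness > 0, brightness_per_um >= 0)
  structure(list(kind = "filament", points = points, thickness = thickness,
                 brightness_per_um = brightness_per_um),
            class = c("scene_filament", "scene_object"))
}

#' @param pitch grid pitch in um.
#' @param line_width grid line width in um.
#' @param z axial position of the (planar) grid in um.
#' @rdname scene_spec
#' @export
scene_grid <- function(pitch = 10, line_width = 0.8, z = 0,
                       brightness_per_um = 2000) {
  stopifnot(pitch > 0, line_width > 0, is.finite(z))
  structure(list(kind = "grid", pitch = pitch, line_width = line_width,
                 z = z, brightness_per_um = brightness_per_um),
            class = c("scene_grid", "scene_object"))
}

#' Brownian-diffusion model of a tracer particle
#'
#' Stokes-Einstein diffusion: `D = k_B * T / (6 * pi * eta * R_p)`; the
#' per-axis displacement variance over one frame is `sigma_D^2 = 2 * D * dt`.
#'
#' @param temperature temperature in K.
#' @param viscosity dynamic viscosity in kg m^-1 s^-1.
#' @param particle_radius particle radius in m.
#' @param frame_period frame period dt in s.
#' @return Object of class `diffusion_model` with the diffusion coefficient
#'   `d_coeff` (m^2 s^-1), `sigma_step_um` (per-axis step sd in um) and the
#'   inputs.
#' @examples
#' dm <- diffusion_model(295, 0.95e-3, 250e-9, 1 / 500)
#' dm$d_coeff * 1e12   # ~0.91 um^2/s
#' @export
diffusion_model <- function(temperature = 295, viscosity = 0.95e-3,
                            particle_radius = 250e-9, frame_period = 1 / 500) {
  stopifnot(temperature >= 0, viscosity > 0, particle_radius > 0,
            frame_period > 0)  # T = 0 gives D = 0 (a frozen particle)
  kb <- 1.380649e-23
  d <- kb * temperature / (6 * pi * viscosity * particle_radius)
  structure(list(temperature = temperature, viscosity = viscosity,
                 particle_radius = particle_radius,
                 frame_period = frame_period, kb = kb, d_coeff = d,
                 sigma_step_um = sqrt(2 * d * frame_period) * 1e6),
            class = "diffusion_model")
}

#' Parameters of a synthetic flagellar beat
#'
#' The beat is generated from a traveling curvature wave
#' `kappa(s, t) = C0 + C1 cos(2 pi f0 t - 2 pi s / lambda_arc)
#'             + C2 cos(4 pi f0 t - 4 pi s / lambda_arc)`
#' integrated into a planar centerline of length `length_um`, plus a traveling
#' sinusoidal out-of-plane displacement whose amplitude ramps linearly from
#' the head.
#'
#' @param c0,c1,c2 curvature components in um^-1 (mean, fundamental and
#'   second-harmonic amplitudes).
#' @param f0 fundamental beat frequency in Hz.
#' @param wavelength_arc arc-length wavelength of the traveling wave, um.
#' @param length_um flagellum length L in um.
#' @param out_of_plane_amplitude peak out-of-plane displacement at the tip, um.
#' @param frame_rate acquisition rate in Hz.
#' @return Object of class `beat_waveform_spec`.
#' @export
beat_waveform_spec <- function(c0 = 0.02, c1 = 0.05, c2 = 0.006, f0 = 25,
                               wavelength_arc = 25, length_um = 50,
                               out_of_plane_amplitude = 1.5,
                               frame_rate = 500) {
  stopifnot(length_um > 0, f0 > 0, c1 >= 0, c2 >= 0, wavelength_arc > 0,
            frame_rate > 0, out_of_plane_amplitude >= 0)
  structure(list(c0 = c0, c1 = c1, c2 = c2, f0 = f0,
                 wavelength_arc = wavelength_arc, length_um = length_um,
                 out_of_plane_amplitude = out_of_plane_amplitude,
                 frame_rate = frame_rate),
            class = "beat_waveform_spec")
}

# Arc-length sampling pitch of synthetic flagella and analysis grids:
# one camera pixel at the default optics (11 um pixel / 32x).
#' @noRd
ARC_PITCH_UM <- 11 / 32
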