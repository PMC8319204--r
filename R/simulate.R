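#' Simulate a Brownian trajectory
#'
#' Per-axis displacements between consecutive frames are i.i.d. normal with
#' mean zero and variance `2 * D * dt` (free diffusion).
#'
#' @param model a [diffusion_model()].
#' @param n_steps number of steps (track has `n_steps + 1` positions).
#' @param start length-3 numeric start position in um.
#' @param seed integer or NULL; reproducible under a fixed seed.
#' @return Data frame with columns `t` (s), `x`, `y`, `z` (um).
#' @export
simulate_brownian_track <- function(model, n_steps, start = c(0, 0, 0),
                                    seed = NULL) {
  stopifnot(inherits(model, "diffusion_model"), n_steps >= 1)
  sd_um <- model$sigma_step_um
  steps <- with_seed(seed, function() {
    matrix(stats::rnorm(3 * n_steps, sd = sd_um), ncol = 3)
  })
  cum <- apply(steps, 2, cumsum)
  if (n_steps == 1) cum <- matrix(cum, nrow = 1)
  pos <- rbind(start, sweep(cum, 2, start, `+`))
  data.frame(t = (0:n_steps) * model$frame_period,
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Simulate a beating flagellum
#'
#' Integrates the traveling curvature wave of a [beat_waveform_spec()] into a
#' planar centerline of fixed length, then adds the out-of-plane component
#' (a traveling sinusoid whose amplitude ramps linearly from the head) and
#' resamples so that the 3D arc length is preserved to better than 0.1% per
#' frame. The head is pinned at `head_xy` and the curve leaves the head along
#' +x.
#'
#' @param spec a [beat_waveform_spec()].
#' @param n_frames number of frames to generate.
#' @param head_xy head position (x, y) in um.
#' @param z0 mean axial position of the flagellum in um.
#' @param pitch arc-length sampling pitch in um (default one camera pixel,
#'   11/32 um).
#' @return List with `frames` (list of n x 3 matrices of (x, y, z) in um),
#'   `s` (arc-length grid in um), `t` (frame times in s), and `kappa`
#'   (matrix of the generating planar curvature, frames x arc points).
#' @export
simulate_flagellar_beat <- function(spec, n_frames, head_xy = c(0, 0),
                                    z0 = 0, pitch = 11 / 32) {
  stopifnot(inherits(spec, "beat_waveform_spec"), n_frames >= 1)
  L <- spec$length_um
  # fine integration grid ending exactly at L (a truncated last step would
  # bias the arc-length rescaling)
  s_fine <- seq(0, L, length.out = ceiling(L / (pitch / 8)) + 1L)
  ds <- s_fine[2] - s_fine[1]
  s_out <- seq(0, L, by = pitch)
  times <- (seq_len(n_frames) - 1) / spec$frame_rate
  kap_tab <- matrix(NA_real_, n_frames, length(s_out))
  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    t <- times[fi]
    kap <- spec$c0 +
      spec$c1 * cos(2 * pi * spec$f0 * t - 2 * pi * s_fine / spec$wavelength_arc) +
      spec$c2 * cos(4 * pi * spec$f0 * t - 4 * pi * s_fine / spec$wavelength_arc)
    # tangent angle = cumulative integral of curvature (trapezoid)
    psi <- c(0, cumsum((kap[-1] + kap[-length(kap)]) / 2 * ds))
    x <- c(0, cumsum((cos(psi[-1]) + cos(psi[-length(psi)])) / 2 * ds))
    y <- c(0, cumsum((sin(psi[-1]) + sin(psi[-length(psi)])) / 2 * ds))
    z <- spec$out_of_plane_amplitude * (s_fine / L) *
      sin(2 * pi * spec$f0 * t - 2 * pi * s_fine / spec$wavelength_arc)
    # restore arc length in 3D: the added z-displacement stretches the curve
    # slightly, so shrink the geometry about the head to length L and
    # resample at a uniform 3D arc pitch
    pts <- cbind(x, y, z)
    seg <- sqrt(rowSums(diff(pts)^2))
    cum3 <- c(0, cumsum(seg))
    scl <- L / cum3[length(cum3)]
    pts <- sweep(pts * scl, 2, c(head_xy[1], head_xy[2], z0), `+`)
    cum3 <- cum3 * scl
    frames[[fi]] <- cbind(
      stats::approx(cum3, pts[, 1], s_out, rule = 2)$y,
      stats::approx(cum3, pts[, 2], s_out, rule = 2)$y,
      stats::approx(cum3, pts[, 3], s_out, rule = 2)$y)
    colnames(frames[[fi]]) <- c("x", "y", "z")
    kap_tab[fi, ] <- stats::approx(s_fine, kap, s_out, rule = 2)$y
  }
  list(frames = frames, s = s_out, t = times, kappa = kap_tab)
}
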