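# Localization precision from Brownian displacement statistics.
#
# Measured displacement distributions are the convolution of the diffusion
# kernel (variance 2*D*dt per axis) with the localization-error distribution,
# so variances add: sigma_M^2 = sigma_P^2 + sigma_D^2.

#' Pooled displacement distribution of tracked particles
#'
#' Pools per-track displacements along one axis at a fixed lag and fits a
#' zero-mean Gaussian by maximum likelihood (`sigma_M^2` = mean squared
#' displacement). A histogram-free second-moment estimate avoids binning
#' choices; [fit_displacement_histogram()] provides the literal PDF-fit
#' cross-check.
#'
#' @param tracks data frame with columns `track`, `frame` and the coordinate
#'   axes (um), e.g. the output of [link_tracks()].
#' @param axis one of "x", "y", "z".
#' @param lag_frames displacement lag in frames (default 1, consecutive
#'   frames).
#' @param min_samples minimum pooled sample count (default 50).
#' @param drift_correct subtract each track's mean displacement (removes a
#'   constant drift velocity).
#' @return Object of class `displacement_distribution`: `axis`, `samples`
#'   (um), `sigma_m2` (um^2), `n`, `lag_frames`.
#' @export
fit_displacement_distribution <- function(tracks, axis = "z", lag_frames = 1L,
                                          min_samples = 50L,
                                          drift_correct = FALSE) {
  stopifnot(axis %in% names(tracks), all(c("track", "frame") %in% names(tracks)))
  samples <- unlist(lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$frame), ]
    v <- tr[[axis]]
    if (length(v) <= lag_frames) return(numeric(0))
    dv <- v[-seq_len(lag_frames)] - v[seq_len(length(v) - lag_frames)]
    if (drift_correct) dv <- dv - mean(dv)
    dv
  }), use.names = FALSE)
  if (length(samples) < min_samples)
    stop("insufficient data: ", length(samples), " displacement samples < ",
         min_samples)
  structure(list(axis = axis, samples = samples,
                 sigma_m2 = mean(samples^2), n = length(samples),
                 lag_frames = lag_frames),
            class = "displacement_distribution")
}

#' Histogram + Gaussian-PDF fit of the displacement distribution
#'
#' Literal curve-fit route: bins the displacements, then least-squares fits
#' the diffusion PDF `P(d) = exp(-d^2 / (2 s2)) / sqrt(2 pi s2)` for the
#' variance `s2`. Used as a cross-check of the second-moment estimator.
#'
#' @param dist a `displacement_distribution`.
#' @param bins number of histogram bins.
#' @return Fitted variance (um^2).
#' @export
fit_displacement_histogram <- function(dist, bins = 41L) {
  stopifnot(inherits(dist, "displacement_distribution"))
  h <- graphics::hist(dist$samples, breaks = bins, plot = FALSE)
  mid <- h$mids; dens <- h$density
  s2_0 <- dist$sigma_m2
  fit <- stats::optimize(function(s2) {
    sum((dens - exp(-mid^2 / (2 * s2)) / sqrt(2 * pi * s2))^2)
  }, interval = c(s2_0 / 25, s2_0 * 25))
  fit$minimum
}

#' Localization precision from a displacement distribution
#'
#' Subtracts the diffusive variance `2 D dt` (Stokes-Einstein D) from the
#' measured displacement variance:
#' `sigma_P = sqrt(sigma_M^2 - k_B T dt / (3 pi eta R))`.
#' If the finite-sample `sigma_M^2` undershoots the diffusive variance, a
#' flagged zero is returned instead of NaN.
#'
#' @param dist a `displacement_distribution`.
#' @param model a [diffusion_model()]; its `frame_period` times
#'   `dist$lag_frames` is the displacement lag.
#' @return List with `sigma_p`, `sigma_m`, `sigma_d` (um), `d_coeff`
#'   (m^2 s^-1), `dt` (s), `n`, `nonphysical` flag.
#' @export
estimate_precision <- function(dist, model) {
  stopifnot(inherits(dist, "displacement_distribution"),
            inherits(model, "diffusion_model"))
  dt <- model$frame_period * dist$lag_frames
  if (dt <= 0) stop("non-positive frame period")
  sigma_d2 <- 2 * model$d_coeff * dt * 1e12          # um^2
  diff2 <- dist$sigma_m2 - sigma_d2
  nonphys <- diff2 < 0
  if (nonphys)
    warning("measured variance below diffusive variance; reporting sigma_p = 0")
  list(sigma_p = sqrt(max(diff2, 0)), sigma_m = sqrt(dist$sigma_m2),
       sigma_d = sqrt(sigma_d2), d_coeff = model$d_coeff, dt = dt,
       n = dist$n, nonphysical = nonphys)
}

#' Per-bead precision table
#'
#' Computes `sigma_M`, `sigma_D`, `sigma_P` separately for every track (the
#' per-bead pathway) in addition to the pooled estimate.
#'
#' @inheritParams fit_displacement_distribution
#' @param model a [diffusion_model()].
#' @return Data frame with one row per track: `track`, `n`, `sigma_m`,
#'   `sigma_p`, `nonphysical`.
#' @export
precision_per_bead <- function(tracks, model, axis = "z", lag_frames = 1L,
                               min_samples = 10L) {
  rows <- lapply(split(tracks, tracks$track), function(tr) {
    d <- tryCatch(
      fit_displacement_distribution(tr, axis, lag_frames,
                                    min_samples = min_samples),
      error = function(e) NULL)
    if (is.null(d)) return(NULL)
    p <- suppressWarnings(estimate_precision(d, model))
    data.frame(track = tr$track[1], n = d$n, sigma_m = p$sigma_m,
               sigma_p = p$sigma_p, nonphysical = p$nonphysical)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
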