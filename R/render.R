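#' Multifocal frame container
#'
#' One timepoint of a multifocal recording: co-registered plane images plus
#' their sample-space focal offsets. Standard recordings carry four planes;
#' degenerate stacks with fewer planes are allowed (e.g. single-plane focus
#' sweeps).
#'
#' @param planes list of equally sized numeric matrices (rows = y, cols = x).
#' @param plane_offsets numeric, focal offset of each plane in um.
#' @param timestamp acquisition time in s.
#' @param pixel_pitch sample-space um per pixel.
#' @return Object of class `multifocal_frame`.
#' @export
multifocal_frame <- function(planes, plane_offsets, timestamp = 0,
                             pixel_pitch = 11 / 32) {
  stopifnot(is.list(planes), length(planes) >= 1)
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all planes must have identical dimensions")
  if (length(plane_offsets) != length(planes) ||
      any(!is.finite(plane_offsets)) || anyDuplicated(plane_offsets))
    stop("plane_offsets must be finite, distinct, one per plane")
  structure(list(planes = planes, plane_offsets = as.numeric(plane_offsets),
                 timestamp = timestamp, pixel_pitch = pixel_pitch),
            class = "multifocal_frame")
}

#' @export
print.multifocal_frame <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("multifocal_frame: %d plane(s) of %d x %d px, offsets [%s] um, t = %g s\n",
              length(x$planes), d[2], d[1],
              paste(signif(x$plane_offsets, 4), collapse = ", "),
              x$timestamp))
  invisible(x)
}

# Add a pixel-integrated 2D Gaussian of total mass `total` centered at
# 0-based pixel coordinates (x0, y0) with isotropic sd sigma (px) to `canvas`.
# The kernel is truncated at 4 sigma.
#' @noRd
splat_gaussian <- function(canvas, x0, y0, sigma, total) {
  if (total <= 0 || sigma <= 0) return(canvas)
  r <- ceiling(4 * sigma)
  nx <- ncol(canvas); ny <- nrow(canvas)
  xs <- max(0, floor(x0 - r)):min(nx - 1, ceiling(x0 + r))
  ys <- max(0, floor(y0 - r)):min(ny - 1, ceiling(y0 + r))
  if (!length(xs) || !length(ys)) return(canvas)
  fx <- stats::pnorm((xs + 0.5 - x0) / sigma) - stats::pnorm((xs - 0.5 - x0) / sigma)
  fy <- stats::pnorm((ys + 0.5 - y0) / sigma) - stats::pnorm((ys - 0.5 - y0) / sigma)
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + total * (fy %o% fx)
  canvas
}

# sd (um) of the object's own footprint, combined in quadrature with the PSF.
#' @noRd
object_sigma_um <- function(ob) {
  switch(ob$kind,
         bead = ob$radius / 2,          # second moment of a uniform disc
         filament = ob$thickness / sqrt(12),  # uniform strip cross-section
         grid = 0,
         0)
}

#' Render one multifocal frame of a synthetic scene
#'
#' Forward model: each object is rendered in each plane as its ideal image
#' convolved with the Gaussian PSF of width `w(z_obj - plane_offset)`
#' (profile `exp(-r^2/w^2)`, i.e. Gaussian sd `w/sqrt(2)`), with
#' energy-conserving normalization, so the integrated noise-free intensity of
#' a point object is identical in all planes. Gaussian read noise (sd = a
#' fraction of the peak noise-free intensity) and optional Poisson noise are
#' applied last, under the scene's seed.
#'
#' @param scene a [scene_spec()].
#' @param config an [optics_config()].
#' @param psf a [gaussian_psf()].
#' @param timestamp frame timestamp in s.
#' @return A [multifocal_frame()] with `length(config$plane_offsets)` planes.
#' @export
render_multifocal_frame <- function(scene, config, psf, timestamp = 0) {
  stopifnot(inherits(scene, "scene_spec"), inherits(config, "optics_config"),
            inherits(psf, "gaussian_psf"))
  pitch <- config$pixel_pitch
  nx <- config$fov_px[1]; ny <- config$fov_px[2]
  offs <- config$plane_offsets
  planes <- lapply(offs, function(off) {
    canvas <- matrix(0, ny, nx)
    for (ob in scene$objects) {
      canvas <- render_object(canvas, ob, off, config, psf)
    }
    canvas
  })
  peak <- max(0, vapply(planes, max, numeric(1)))
  planes <- lapply(planes, function(p) p + scene$background_level)
  nsd <- scene$noise_sd %||% (scene$noise_sd_frac * peak)
  if (nsd > 0 || scene$poisson) {
    planes <- with_seed(scene$seed, function() {
      lapply(planes, function(p) {
        if (scene$poisson) p[] <- stats::rpois(length(p), pmax(p, 0))
        if (nsd > 0) p <- p + stats::rnorm(length(p), sd = nsd)
        p
      })
    })
  }
  multifocal_frame(planes, offs, timestamp = timestamp, pixel_pitch = pitch)
}

#' @noRd
render_object <- function(canvas, ob, plane_off, config, psf) {
  pitch <- config$pixel_pitch
  sig_obj <- object_sigma_um(ob)
  if (ob$kind == "bead") {
    sig_psf <- psf_width(ob$center[3] - plane_off, psf) / sqrt(2)
    sigma_px <- sqrt(sig_psf^2 + sig_obj^2) / pitch
    return(splat_gaussian(canvas, ob$center[1] / pitch, ob$center[2] / pitch,
                          sigma_px, ob$brightness))
  }
  if (ob$kind == "filament") {
    # resample the polyline at a fine 3D arc-length step and splat each sample
    pts <- ob$points
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    total_len <- cum[length(cum)]
    # one splat per pixel pitch of arc: the PSF sd is always >= 4 px here,
    # so the Gaussian comb is indistinguishable from a continuous line
    ds <- pitch
    s_new <- seq(0, total_len, by = ds)
    xi <- stats::approx(cum, pts[, 1], s_new)$y
    yi <- stats::approx(cum, pts[, 2], s_new)$y
    zi <- stats::approx(cum, pts[, 3], s_new)$y
    w_z <- psf_width(zi - plane_off, psf) / sqrt(2)
    sigma_px <- sqrt(w_z^2 + sig_obj^2) / pitch
    mass <- ob$brightness_per_um * ds
    for (i in seq_along(s_new)) {
      canvas <- splat_gaussian(canvas, xi[i] / pitch, yi[i] / pitch,
                               sigma_px[i], mass)
    }
    return(canvas)
  }
  if (ob$kind == "grid") {
    nx <- ncol(canvas); ny <- nrow(canvas)
    sig_psf <- psf_width(ob$z - plane_off, psf) / sqrt(2)
    sigma_um <- max(sqrt(sig_psf^2 + sig_obj^2), 1e-6)
    rho <- ob$brightness_per_um / ob$line_width   # per-area brightness
    val <- rho * pitch^2
    hw <- ob$line_width / 2
    strip <- function(coord_um, center) {
      stats::pnorm((coord_um - center + hw) / sigma_um) -
        stats::pnorm((coord_um - center - hw) / sigma_um)
    }
    x_um <- (seq_len(nx) - 1) * pitch
    y_um <- (seq_len(ny) - 1) * pitch
    for (cx in seq(0, (nx - 1) * pitch, by = ob$pitch)) {
      canvas <- canvas + val * (rep(1, ny) %o% strip(x_um, cx))
    }
    for (cy in seq(0, (ny - 1) * pitch, by = ob$pitch)) {
      canvas <- canvas + val * (strip(y_um, cy) %o% rep(1, nx))
    }
    return(canvas)
  }
  canvas
}

#' Render a z-stack of one immobile bead
#'
#' Convenience wrapper used for radius-vs-z calibration experiments: renders
#' the same bead at a sequence of piezo positions. Moving the objective up by
#' `dz` is equivalent to moving the bead by `dz` relative to the focal planes.
#'
#' @param piezo_z numeric vector of piezo positions (um).
#' @param config,psf optics and PSF model.
#' @param xy bead lateral position in um (defaults to the FOV center).
#' @param bead a [scene_bead()] template (its z is overridden per step).
#' @param noise_sd_frac,seed noise controls passed to [scene_spec()].
#' @return List of [multifocal_frame()]s, one per piezo position.
#' @export
render_bead_zstack <- function(piezo_z, config, psf, xy = NULL,
                               bead = scene_bead(c(0, 0, 0)),
                               noise_sd_frac = 0.02, seed = NULL) {
  if (is.null(xy)) {
    xy <- (config$fov_px - 1) / 2 * config$pixel_pitch
  }
  lapply(seq_along(piezo_z), function(i) {
    b <- scene_bead(c(xy[1], xy[2], piezo_z[i]), radius = bead$radius,
                    brightness = bead$brightness)
    sc <- scene_spec(list(b), noise_sd_frac = noise_sd_frac,
                     seed = if (is.null(seed)) NULL else seed + i)
    render_multifocal_frame(sc, config, psf, timestamp = i - 1)
  })
}
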