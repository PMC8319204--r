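# Bead detection, intensity-weighted algebraic circle fitting,
# radius-vs-z calibration, z-inference and track linking.

#' Maximum-intensity projection and static-background removal
#'
#' Per timepoint, a pixelwise maximum across the planes is formed (detection
#' works on this projection video). With `subtract_static`, the per-pixel
#' time-average is subtracted from every projection frame and from every
#' plane (negatives clipped at 0), removing immobile beads and background
#' structures.
#'
#' @param frames list of [multifocal_frame()]s.
#' @param subtract_static logical; requires >= 2 frames.
#' @return List with `projection` (list of matrices) and `frames` (the
#'   cleaned multifocal frames).
#' @export
preprocess_video <- function(frames, subtract_static = FALSE) {
  stopifnot(length(frames) >= 1)
  if (subtract_static && length(frames) < 2)
    stop("static subtraction requires at least 2 frames")
  proj <- lapply(frames, function(fr) Reduce(pmax, fr$planes))
  if (subtract_static) {
    mean_proj <- Reduce(`+`, proj) / length(proj)
    proj <- lapply(proj, function(p) pmax(p - mean_proj, 0))
    n_pl <- length(frames[[1]]$planes)
    for (k in seq_len(n_pl)) {
      mk <- Reduce(`+`, lapply(frames, function(fr) fr$planes[[k]])) /
        length(frames)
      for (i in seq_along(frames)) {
        frames[[i]]$planes[[k]] <- pmax(frames[[i]]$planes[[k]] - mk, 0)
      }
    }
  }
  list(projection = proj, frames = frames)
}

#' Laplacian-of-Gaussian blob detection with subpixel refinement
#'
#' Blobs of the given diameter are detected as maxima of the scale-normalized
#' negative-LoG response at `sigma = diameter / (2 * sqrt(2))`, thresholded,
#' non-maximum suppressed within one diameter, and refined to subpixel by a
#' 2D quadratic fit.
#'
#' @param image 2D numeric matrix (typically a max projection).
#' @param diameter_px expected blob diameter in px (>= 3).
#' @param threshold minimum LoG response (same units as image counts).
#' @return Data frame with 0-based subpixel `x`, `y` and `response`; empty if
#'   nothing detected.
#' @export
detect_beads <- function(image, diameter_px = 10, threshold = 50) {
  stopifnot(diameter_px >= 3)
  sigma <- diameter_px / (2 * sqrt(2))
  resp <- log_response(image, sigma)
  cand <- local_maxima(resp, radius = max(1L, round(diameter_px)))
  cand <- cand[cand$value > threshold, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  ref <- t(mapply(function(ix, iy) subpixel_peak(resp, ix, iy),
                  cand$ix, cand$iy))
  data.frame(x = ref[, 1], y = ref[, 2], response = cand$value)
}

#' Extract a circular pixel patch around a seed center
#'
#' @param image 2D numeric matrix.
#' @param cx,cy 0-based seed center (px).
#' @param radius_px patch radius (default 10 px).
#' @return Data frame with pixel coordinates `x`, `y` (0-based) and
#'   intensities `I`.
#' @export
circle_patch <- function(image, cx, cy, radius_px = 10) {
  nx <- ncol(image); ny <- nrow(image)
  xs <- max(0, floor(cx - radius_px)):min(nx - 1, ceiling(cx + radius_px))
  ys <- max(0, floor(cy - radius_px)):min(ny - 1, ceiling(cy + radius_px))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radius_px^2
  g <- g[keep, , drop = FALSE]
  g$I <- image[cbind(g$y + 1, g$x + 1)]
  g
}

#' Intensity-weighted algebraic circle fit
#'
#' Fits the linearized circle equation `2 x xc + 2 y yc + b = x^2 + y^2` by
#' least squares with each row weighted by the squared pixel intensity, and
#' recovers the radius as `R = sqrt(xc^2 + yc^2 + b)`. The goodness `r2` is
#' computed on the weighted linearized residuals.
#'
#' @param patch data frame with columns `x`, `y`, `I` (see [circle_patch()]).
#' @return List with `xc`, `yc`, `b`, `radius`, `r2`, and `valid` (FALSE when
#'   `xc^2 + yc^2 + b < 0`, an unusable radius).
#' @export
fit_circle_weighted <- function(patch) {
  x <- patch$x; y <- patch$y; w <- patch$I^2
  if (length(x) < 3) stop("circle fit needs at least 3 pixels")
  A <- cbind(2 * x, 2 * y, 1) * w
  B <- (x^2 + y^2) * w
  qr_A <- qr(A)
  if (qr_A$rank < 3) stop("singular circle fit: collinear/degenerate pixels")
  cf <- qr.coef(qr_A, B)
  rss <- sum((A %*% cf - B)^2)
  tss <- sum((B - mean(B))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  rsq <- cf[1]^2 + cf[2]^2 + cf[3]
  list(xc = unname(cf[1]), yc = unname(cf[2]), b = unname(cf[3]),
       radius = if (rsq >= 0) sqrt(rsq) else NA_real_,
       r2 = r2, valid = rsq >= 0)
}

#' Measure per-plane bead radii in one multifocal frame
#'
#' Applies [circle_patch()] + [fit_circle_weighted()] around a seed position
#' in every plane.
#'
#' @param frame a [multifocal_frame()].
#' @param cx,cy 0-based seed center in px.
#' @param radius_px patch radius (default 10).
#' @return Data frame with one row per plane: `plane`, `radius`, `r2`,
#'   `valid`.
#' @export
measure_bead_radii <- function(frame, cx, cy, radius_px = 10) {
  res <- lapply(seq_along(frame$planes), function(k) {
    f <- tryCatch(
      fit_circle_weighted(circle_patch(frame$planes[[k]], cx, cy, radius_px)),
      error = function(e) list(radius = NA_real_, r2 = -Inf, valid = FALSE))
    data.frame(plane = k, radius = f$radius, r2 = f$r2, valid = isTRUE(f$valid))
  })
  do.call(rbind, res)
}

#' Radius-versus-z calibration from bead focus sweeps
#'
#' Per-bead radius profiles are aligned in z by least-mean-square profile
#' matching (integer grid search plus parabolic refinement), averaged on the
#' common z grid, and smoothed by a centered moving average. The across-bead
#' spread `sigma_R(z)` propagates to a z-precision via the inverse-function
#' rule `sigma_z = sigma_R / |dR/dz|`.
#'
#' @param profiles list (one per bead) of matrices `n_z x n_planes` of
#'   measured radii (px); rows follow `piezo_z`.
#' @param piezo_z piezo positions (um), uniform grid.
#' @param smooth_um moving-average window in um (default 2). The physical
#'   radius-vs-z curve varies on the Rayleigh-range scale (tens of um), so a
#'   window of a couple of um suppresses bead-noise wiggles without biasing
#'   the curve.
#' @param max_shift_um largest bead-to-bead z-offset searched (default 2).
#' @return Object of class `radius_calibration`: `z` (um), `r` (n_z x
#'   n_planes smoothed mean radius, px), `sigma_r`, `sigma_z`, `offsets`
#'   (per-bead alignment shifts, um).
#' @export
build_radius_calibration <- function(profiles, piezo_z, smooth_um = 2,
                                     max_shift_um = 2) {
  stopifnot(length(profiles) >= 1)
  dz <- stats::median(diff(piezo_z))
  n_planes <- ncol(profiles[[1]])
  ref <- profiles[[1]]
  offsets <- numeric(length(profiles))
  aligned <- vector("list", length(profiles))
  aligned[[1]] <- ref
  shift_profile <- function(pr, off) {
    apply(pr, 2, function(col) {
      stats::approx(piezo_z + off, col, piezo_z, rule = 1)$y
    })
  }
  if (length(profiles) > 1) {
    max_k <- max(1L, round(max_shift_um / abs(dz)))
    for (i in seq_along(profiles)[-1]) {
      cost <- vapply(-max_k:max_k, function(k) {
        sh <- shift_profile(profiles[[i]], k * dz)
        mean((sh - ref)^2, na.rm = TRUE)
      }, numeric(1))
      j <- which.min(cost)
      off <- (-max_k:max_k)[j] * dz
      if (j > 1 && j < length(cost)) {  # parabolic refinement
        den <- cost[j - 1] - 2 * cost[j] + cost[j + 1]
        if (den > 0) off <- off + dz * 0.5 * (cost[j - 1] - cost[j + 1]) / den * sign(dz)
      }
      offsets[i] <- off
      aligned[[i]] <- shift_profile(profiles[[i]], off)
      if (all(is.na(aligned[[i]])))
        stop("alignment error: non-overlapping radius profiles")
    }
  }
  arr <- simplify2array(aligned)               # n_z x n_planes x n_beads
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  r_mean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sigma_r <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) else 0
  })
  w <- max(1L, 2L * floor(smooth_um / abs(dz) / 2) + 1L)  # odd window
  r_smooth <- apply(r_mean, 2, moving_average, w = w)
  # local-linear (Savitzky-Golay order 1) slope over the smoothing window;
  # precision diverges where dR/dz -> 0
  drdz <- apply(r_smooth, 2, sg_slope, w = max(w, 5L), dx = dz)
  sigma_z <- abs(sigma_r / drdz)
  sigma_z[!is.finite(sigma_z)] <- Inf
  structure(list(z = piezo_z, r = r_smooth, sigma_r = sigma_r,
                 sigma_z = sigma_z, offsets = offsets),
            class = "radius_calibration")
}

#' Combined z-precision over a plane subset
#'
#' The best plane can be chosen at every depth, so the combined precision is
#' the pointwise minimum of the per-plane `sigma_z(z)` curves.
#'
#' @param calibration a [build_radius_calibration()] result.
#' @param planes_used integer vector of plane indices.
#' @return List with `z`, `sigma_z` (combined curve) and `mean_sigma_z`
#'   (mean over depths where the combined value is finite).
#' @export
predict_z_precision <- function(calibration,
                                planes_used = seq_len(ncol(calibration$r))) {
  stopifnot(inherits(calibration, "radius_calibration"))
  if (!length(planes_used)) stop("empty plane subset")
  sz <- calibration$sigma_z[, planes_used, drop = FALSE]
  comb <- apply(sz, 1, min)
  list(z = calibration$z, sigma_z = comb,
       mean_sigma_z = mean(comb[is.finite(comb)]))
}

# Minima of the difference function |r_meas - R_k(z)|: one candidate on
# each side of the calibration curve's minimum. Each branch is made
# monotone (cumulative-max envelope moving away from the focus) before a
# linear-interpolation inversion, which keeps the candidates stable against
# residual noise wiggles in the calibrated curve. A radius below the curve
# minimum yields the single candidate at the focus; a radius above a
# branch's maximum yields the (flagged) branch boundary.
#' @noRd
difference_minima <- function(z, curve, r_meas) {
  i0 <- which.min(curve)
  if (r_meas <= curve[i0]) {
    # radius at/below the curve minimum: the single at-focus candidate
    return(structure(z[i0], boundary = FALSE, below_min = r_meas < curve[i0]))
  }
  invert_branch <- function(ids) {
    if (length(ids) < 2) return(NULL)
    vals <- cummax(curve[ids])          # monotone away from the focus
    zb <- z[ids]
    nb <- length(vals)
    if (r_meas >= vals[nb]) {
      # radius beyond the calibrated branch: extrapolate a little with the
      # branch-end slope (flagged), so near-edge beads keep a usable
      # candidate instead of an artificial clamp at the grid boundary
      tail_n <- min(nb, max(5L, nb %/% 10L))
      slope <- (vals[nb] - vals[nb - tail_n + 1L]) /
        (zb[nb] - zb[nb - tail_n + 1L])
      zc <- if (is.finite(slope) && abs(slope) > 1e-9)
        zb[nb] + (r_meas - vals[nb]) / slope else zb[nb]
      lim <- 25                                   # sanity cap, um
      zc <- max(min(zc, zb[nb] + lim), zb[nb] - lim)
      return(list(z = zc, boundary = TRUE))
    }
    j <- which(vals >= r_meas)[1]
    if (j == 1) return(list(z = zb[1], boundary = FALSE))
    frac <- (r_meas - vals[j - 1]) / (vals[j] - vals[j - 1])
    list(z = zb[j - 1] + frac * (zb[j] - zb[j - 1]), boundary = FALSE)
  }
  left <- invert_branch(rev(seq_len(i0)))
  right <- invert_branch(i0:length(curve))
  zc <- c(left$z, right$z)
  bd <- c(left$boundary, right$boundary)
  keep <- !duplicated(zc)
  structure(zc[keep], boundary = bd[keep])
}

#' @noRd
sigma_z_at <- function(calibration, plane, z) {
  stats::approx(calibration$z, calibration$sigma_z[, plane], z, rule = 2)$y
}

# Shared cross-plane candidate resolver (used for beads and flagellar
# points). `cands` is a list of numeric candidate vectors with a per-element
# "boundary" attribute; `sigma_fun(i, z)` returns the propagated precision of
# list element i at depth z. Selection: exhaustive one-candidate-per-element
# combinations, minimizing the precision-weighted dispersion; the result is
# the precision-weighted mean of the winning members.
#' @noRd
resolve_z_combination <- function(cands, sigma_fun, sigma_floor = 0.05,
                                  boundary_sigma = 1) {
  m <- length(cands)
  grid <- expand.grid(lapply(cands, seq_along))
  score <- apply(grid, 1, function(sel) {
    zs <- numeric(m); sig <- numeric(m)
    for (i in seq_len(m)) {
      cv <- cands[[i]]
      zs[i] <- cv[sel[i]]
      sig[i] <- max(sigma_fun(i, zs[i]), sigma_floor)
      if (isTRUE(attr(cv, "boundary")[sel[i]])) {
        sig[i] <- max(sig[i], boundary_sigma)
      }
    }
    wts <- 1 / sig^2
    mu <- sum(wts * zs) / sum(wts)
    c(disp = sqrt(sum(wts * (zs - mu)^2) / sum(wts)), mean = mu)
  })
  disp <- score["disp", ]
  best <- which(disp <= min(disp) + 1e-12)
  list(best = best, grid = grid, score = score)
}

#' Infer a bead's z-position from per-plane radii
#'
#' Planes with fit quality `r2 <= r2_min` (default 0.8) or an invalid radius
#' are discarded; a bead with fewer than two valid planes is excluded. Each
#' valid plane's difference function `|R_meas - R_k(z)|` contributes up to
#' two candidate z-positions (one either side of that plane's focus; radii
#' beyond the calibrated range extrapolate with the branch-end slope,
#' flagged). The cross-plane candidate combination with the lowest
#' precision-weighted dispersion is selected, and the final z is the
#' precision-weighted mean of its members (weights from the calibrated
#' error propagation, so planes measuring in the flat region near their own
#' focus contribute little). The reported `sigma_z` is that of the most
#' precise plane at the inferred depth, matching [predict_z_precision()].
#'
#' @param radii data frame from [measure_bead_radii()] (columns `plane`,
#'   `radius`, `r2`, `valid`).
#' @param calibration a [build_radius_calibration()] result covering the
#'   plausible z-range. Calibration z is expressed as bead z relative to
#'   plane 1; each plane's curve already encodes its focal offset.
#' @param r2_min plane-validity threshold on the fit quality.
#' @return List with `z`, `sigma_z`, `plane` (plane supplying the final z),
#'   `planes_used`, `candidates` (per-plane list), `excluded`, `reason`,
#'   `ambiguous`.
#' @export
infer_bead_z <- function(radii, calibration, r2_min = 0.8) {
  stopifnot(inherits(calibration, "radius_calibration"))
  ok <- radii$valid & radii$r2 > r2_min & is.finite(radii$radius)
  planes <- radii$plane[ok]
  out <- list(z = NA_real_, sigma_z = NA_real_, plane = NA_integer_,
              planes_used = planes, candidates = NULL,
              excluded = FALSE, reason = NA_character_, ambiguous = FALSE)
  cands <- lapply(seq_along(planes), function(i) {
    k <- planes[i]
    difference_minima(calibration$z, calibration$r[, k],
                      radii$radius[radii$plane == k])
  })
  names(cands) <- as.character(planes)
  out$candidates <- cands
  if (length(planes) < 2) {
    out$excluded <- TRUE
    out$reason <- "insufficient valid planes"
    out$ambiguous <- length(planes) == 1 && length(cands[[1]]) > 1
    return(out)
  }
  # exhaustive search over one-candidate-per-plane combinations; see
  # resolve_z_combination for the selection rule
  rc <- resolve_z_combination(cands, function(i, zz) {
    sigma_z_at(calibration, planes[i], zz)
  })
  grid <- rc$grid; score <- rc$score; best <- rc$best
  if (length(best) > 1) {
    # tie-break: combination whose mean z has the better combined precision
    comb_sz <- vapply(best, function(b) {
      min(vapply(planes, function(k) {
        sigma_z_at(calibration, k, score["mean", b])
      }, numeric(1)))
    }, numeric(1))
    best <- best[which.min(comb_sz)]
  }
  z_final <- score["mean", best]
  per_plane_sz <- vapply(planes, function(k) {
    sigma_z_at(calibration, k, z_final)
  }, numeric(1))
  ibest <- which.min(per_plane_sz)
  out$z <- unname(z_final)
  out$sigma_z <- per_plane_sz[ibest]
  out$plane <- planes[ibest]
  out$planes_used <- planes
  out
}

#' Link per-frame 3D detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames; links
#' of 3D distance >= `max_dist` are forbidden and unlinked detections start
#' new tracks.
#'
#' @param detections data frame with columns `frame`, `x`, `y`, `z` (um),
#'   time-sorted.
#' @param max_dist linking radius in um (default 1.5).
#' @return The input with an integer `track` column prepended.
#' @export
link_tracks <- function(detections, max_dist = 1.5) {
  d <- as.data.frame(detections)
  stopifnot(all(c("frame", "x", "y", "z") %in% names(d)))
  d <- d[order(d$frame), , drop = FALSE]
  d$track <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(d$frame))
  idx_prev <- which(d$frame == frames[1])
  d$track[idx_prev] <- seq_len(length(idx_prev))
  next_id <- length(idx_prev) + 1L
  for (fi in seq_along(frames)[-1]) {
    idx_cur <- which(d$frame == frames[fi])
    prev_xyz <- as.matrix(d[idx_prev, c("x", "y", "z")])
    cur_xyz <- as.matrix(d[idx_cur, c("x", "y", "z")])
    if (length(idx_prev) && length(idx_cur)) {
      fwd <- FNN::get.knnx(cur_xyz, prev_xyz, k = 1)     # prev -> cur
      bwd <- FNN::get.knnx(prev_xyz, cur_xyz, k = 1)     # cur -> prev
      for (j in seq_along(idx_cur)) {
        p <- bwd$nn.index[j, 1]
        mutual <- fwd$nn.index[p, 1] == j
        if (mutual && bwd$nn.dist[j, 1] < max_dist) {
          d$track[idx_cur[j]] <- d$track[idx_prev[p]]
        }
      }
    }
    un <- idx_cur[is.na(d$track[idx_cur])]
    if (length(un)) {
      d$track[un] <- seq.int(next_id, length.out = length(un))
      next_id <- next_id + length(un)
    }
    idx_prev <- idx_cur
  }
  d[, c("track", setdiff(names(d), "track"))]
}
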