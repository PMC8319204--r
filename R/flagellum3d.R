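# Flagellum reconstruction: 2D centerline tracing on the sharpest plane,
# per-plane width/intensity profiling, calibrated z-inference.

#' Index of the sharpest plane
#'
#' Sharpness is the standard deviation of pixel intensity within the ROI;
#' ties break to the lowest plane index. The measure is invariant to a
#' uniform intensity offset.
#'
#' @param frame a [multifocal_frame()].
#' @param roi optional list with `x` and `y` 0-based index ranges
#'   (`c(min, max)`); NULL uses the full image.
#' @return Integer plane index.
#' @export
select_sharpest_plane <- function(frame, roi = NULL) {
  stopifnot(inherits(frame, "multifocal_frame"))
  sds <- vapply(frame$planes, function(p) {
    if (!is.null(roi)) {
      p <- p[(roi$y[1]:roi$y[2]) + 1, (roi$x[1]:roi$x[2]) + 1, drop = FALSE]
    }
    if (!length(p)) stop("empty roi")
    stats::sd(p)
  }, numeric(1))
  which.max(sds)  # which.max returns the first (lowest) index on ties
}

# Longest path through an 8-connected skeleton via double BFS.
# Returns ordered 0-based (x, y) coordinates.
#' @noRd
skeleton_longest_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2) return(NULL)
  nr <- nrow(skel)
  key <- (idx[, 2] - 1) * nr + idx[, 1]      # col-major linear key
  lookup <- integer(0)
  lookup[key] <- seq_len(n)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  nbrs <- lapply(seq_len(n), function(i) {
    r <- idx[i, 1] + offs$dy; c <- idx[i, 2] + offs$dx
    ok <- r >= 1 & r <= nr & c >= 1 & c <= ncol(skel)
    k <- (c[ok] - 1) * nr + r[ok]
    v <- lookup[k]
    v[!is.na(v) & v > 0]
  })
  bfs <- function(start) {
    dist <- rep(-1L, n); parent <- rep(NA_integer_, n)
    dist[start] <- 0L
    q <- start
    while (length(q)) {
      cur <- q[1]; q <- q[-1]
      for (nb in nbrs[[cur]]) {
        if (dist[nb] < 0) {
          dist[nb] <- dist[cur] + 1L
          parent[nb] <- cur
          q <- c(q, nb)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  e1 <- which.max(b1$dist)
  b2 <- bfs(e1)
  e2 <- which.max(b2$dist)
  path <- integer(0)
  cur <- e2
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- b2$parent[cur]
  }
  cbind(x = idx[path, 2] - 1, y = idx[path, 1] - 1)
}

#' Trace a flagellar centerline in 2D
#'
#' Workflow: Gaussian blur, Li threshold, skeletonization, pruning to the
#' longest skeleton path, smoothing-spline fit, resampling at a fixed
#' arc-length pitch, and head assignment to the endpoint with the larger
#' local integrated intensity.
#'
#' @param image 2D numeric matrix (the sharpest plane).
#' @param pixel_pitch um per px.
#' @param blur_sigma_px pre-segmentation blur (default 1).
#' @param pitch_um arc-length resampling pitch (default 11/32 um).
#' @param min_length_um minimum accepted centerline length (default 20).
#' @param spline_df_per_um spline flexibility (default 0.4 df per um).
#' @param head_anchor re-zero the arc length at the intensity centroid of
#'   the head region (stabilizes the s-origin across frames when a bright
#'   head is present; default TRUE).
#' @return Object of class `flagellum_trace`: data frame `points` with
#'   0-based subpixel `x`, `y` (px) and arc length `s` (um, 0 at head), plus
#'   `pixel_pitch`.
#' @export
extract_centerline_2d <- function(image, pixel_pitch = 11 / 32,
                                  blur_sigma_px = 1, pitch_um = 11 / 32,
                                  min_length_um = 20,
                                  spline_df_per_um = 0.4,
                                  head_anchor = TRUE) {
  sm <- gaussian_blur(image, blur_sigma_px)
  mask <- sm > li_threshold(sm)
  if (!any(mask)) stop("no flagellum found: empty segmentation")
  if (mean(mask) > 0.25)
    stop("no flagellum found: no dominant filamentous structure ",
         "(threshold segments ", round(100 * mean(mask)), "% of the image)")
  path <- skeleton_longest_path(skeletonize_zs(mask))
  if (is.null(path) || nrow(path) < 5)
    stop("no flagellum found: skeleton too short")
  chord <- c(0, cumsum(sqrt(rowSums(diff(path)^2)))) * pixel_pitch
  total <- chord[length(chord)]
  if (total < min_length_um)
    stop("no flagellum found: skeleton length ", round(total, 1),
         " um < ", min_length_um, " um")
  df <- max(4, min(round(total * spline_df_per_um), nrow(path) - 2))
  fx <- stats::smooth.spline(chord, path[, 1], df = df)
  fy <- stats::smooth.spline(chord, path[, 2], df = df)
  # resample at fixed arc-length pitch on the smoothed curve
  s_dense <- seq(0, total, length.out = max(200L, nrow(path) * 2L))
  xd <- stats::predict(fx, s_dense)$y
  yd <- stats::predict(fy, s_dense)$y
  arc <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2))) * pixel_pitch
  s_out <- seq(0, arc[length(arc)], by = pitch_um)
  x_out <- stats::approx(arc, xd, s_out, rule = 2)$y
  y_out <- stats::approx(arc, yd, s_out, rule = 2)$y
  # refine to the intensity ridge: per point, fit a Gaussian to the profile
  # along the local normal and shift by its center, then re-smooth. The
  # skeleton is quantized to ~0.5 px; the refined centerline is good to a
  # small fraction of a pixel, which curvature analysis needs.
  for (pass in 1:2) {
    n <- length(x_out)
    if (n < 5) break
    tx <- c(x_out[2] - x_out[1], (x_out[3:n] - x_out[1:(n - 2)]) / 2,
            x_out[n] - x_out[n - 1])
    ty <- c(y_out[2] - y_out[1], (y_out[3:n] - y_out[1:(n - 2)]) / 2,
            y_out[n] - y_out[n - 1])
    tl <- sqrt(tx^2 + ty^2)
    nxv <- -ty / tl; nyv <- tx / tl
    u <- -8:8
    for (i in seq_len(n)) {
      v <- bilinear_sample(sm, x_out[i] + u * nxv[i], y_out[i] + u * nyv[i])
      ok <- !is.na(v)
      if (sum(ok) < 7) next
      f <- gauss_profile_fit(u[ok], v[ok])
      if (!f$flagged && is.finite(f$center) && abs(f$center) < 2.5) {
        x_out[i] <- x_out[i] + f$center * nxv[i]
        y_out[i] <- y_out[i] + f$center * nyv[i]
      }
    }
    fx2 <- stats::smooth.spline(s_out, x_out, df = df)
    fy2 <- stats::smooth.spline(s_out, y_out, df = df)
    x_out <- stats::predict(fx2, s_out)$y
    y_out <- stats::predict(fy2, s_out)$y
  }
  # extend both ends along the local tangent to the half-plateau intensity
  # contour: thresholding erodes the blurred filament ends by ~1 PSF width,
  # and the line-spread function drops to half its plateau value exactly at
  # the physical end of the filament
  plateau <- stats::median(bilinear_sample(sm, x_out, y_out), na.rm = TRUE)
  extend_end <- function(x_out, y_out, head) {
    n <- length(x_out)
    idx <- if (head) seq_len(min(6, n)) else seq(max(1, n - 5), n)
    dx <- x_out[max(idx)] - x_out[min(idx)]
    dy <- y_out[max(idx)] - y_out[min(idx)]
    dl <- sqrt(dx^2 + dy^2)
    if (dl < 1e-9) return(list(x = x_out, y = y_out))
    dirx <- dx / dl * (if (head) -1 else 1)
    diry <- dy / dl * (if (head) -1 else 1)
    px <- if (head) x_out[1] else x_out[n]
    py <- if (head) y_out[1] else y_out[n]
    step <- (pitch_um / pixel_pitch) / 2
    add_x <- c(); add_y <- c()
    for (i in seq_len(round(5 / pitch_um * 2))) {    # at most 5 um
      qx <- px + i * step * dirx
      qy <- py + i * step * diry
      v <- bilinear_sample(sm, qx, qy)
      if (is.na(v) || v < 0.5 * plateau) break
      add_x <- c(add_x, qx); add_y <- c(add_y, qy)
    }
    if (head) list(x = c(rev(add_x), x_out), y = c(rev(add_y), y_out))
    else list(x = c(x_out, add_x), y = c(y_out, add_y))
  }
  for (head_end in c(TRUE, FALSE)) {
    ext <- extend_end(x_out, y_out, head_end)
    x_out <- ext$x; y_out <- ext$y
  }
  # back to a uniform arc-length grid
  arc2 <- c(0, cumsum(sqrt(diff(x_out)^2 + diff(y_out)^2))) * pixel_pitch
  s_out <- seq(0, arc2[length(arc2)], by = pitch_um)
  x_out <- stats::approx(arc2, x_out, s_out, rule = 2)$y
  y_out <- stats::approx(arc2, y_out, s_out, rule = 2)$y
  # head = endpoint with larger local integrated intensity
  ends <- rbind(c(x_out[1], y_out[1]),
                c(x_out[length(x_out)], y_out[length(y_out)]))
  r_px <- 3 / pixel_pitch
  endsum <- apply(ends, 1, function(e) {
    patch <- circle_patch(sm, e[1], e[2], r_px)
    sum(patch$I)
  })
  if (endsum[2] > endsum[1]) {
    x_out <- rev(x_out); y_out <- rev(y_out)
  }
  if (head_anchor) {
    # re-zero s at the intensity-squared centroid of the head region, which
    # is much more stable frame-to-frame than the raw skeleton endpoint
    patch <- circle_patch(sm, x_out[1], y_out[1], 2 / pixel_pitch)
    w2 <- patch$I^2
    if (sum(w2) > 0) {
      cx <- sum(w2 * patch$x) / sum(w2)
      cy <- sum(w2 * patch$y) / sum(w2)
      i0 <- which.min((x_out - cx)^2 + (y_out - cy)^2)
      if (i0 > 1) {
        x_out <- x_out[i0:length(x_out)]
        y_out <- y_out[i0:length(y_out)]
      }
    }
  }
  s_out <- (seq_along(x_out) - 1) * pitch_um
  structure(list(points = data.frame(x = x_out, y = y_out, s = s_out),
                 pixel_pitch = pixel_pitch),
            class = "flagellum_trace")
}

# 1D Gaussian peak estimate on a profile sampled at `u` (px). Baseline from
# the outer 15% of samples (dark-field backgrounds are near zero), then an
# intensity^2-weighted log-parabola fit of the upper part of the peak:
# ln v = a0 + a1 u + a2 u^2 with sd = sqrt(-1/(2 a2)). Exact for a Gaussian
# profile and, unlike truncated moments, keeps full sensitivity of the
# fitted width to defocus. Falls back to weighted moments when degenerate.
#' @noRd
gauss_profile_fit <- function(u, v) {
  n <- length(v)
  ne <- max(2L, round(0.15 * n))
  edge <- c(v[seq_len(ne)], v[seq(n - ne + 1L, n)])
  offset <- stats::median(edge)
  noise <- stats::sd(edge)
  v1 <- v - offset
  amp <- max(v1)
  flagged <- !is.finite(amp) ||
    amp <= max(3 * ifelse(is.finite(noise), noise, 0),
               1e-6 * max(abs(offset), 1))
  if (flagged) {
    return(list(amp = amp, center = NA_real_, sd = NA_real_,
                offset = offset, flagged = TRUE))
  }
  log_parab <- function(v1) {
    sel <- which(v1 > 0.15 * max(v1))
    if (length(sel) < 5) return(NULL)
    us <- u[sel]; vs <- v1[sel]
    X <- cbind(1, us, us^2) * vs          # weights vs^2 in the LS sense
    co <- tryCatch(qr.coef(qr(X), vs * log(vs)), error = function(e) NULL)
    if (is.null(co) || !is.finite(co[3]) || co[3] >= 0) return(NULL)
    list(center = -co[2] / (2 * co[3]), sd = sqrt(-1 / (2 * co[3])),
         amp = exp(co[1] - co[2]^2 / (4 * co[3])))
  }
  fit <- log_parab(v1)
  # refine the baseline: the outer-sample median clips Gaussian tails when
  # the window is only ~2.5 sd wide, shrinking the fitted width; with the
  # shape known, amplitude and offset follow from a linear solve
  if (!is.null(fit)) {
    for (pass in 1:2) {
      g <- exp(-(u - fit$center)^2 / (2 * fit$sd^2))
      co2 <- tryCatch(qr.coef(qr(cbind(g, 1)), v), error = function(e) NULL)
      if (is.null(co2) || !is.finite(co2[2]) || co2[1] <= 0) break
      offset <- unname(co2[2])
      amp <- unname(co2[1])
      fit2 <- log_parab(v - offset)
      if (is.null(fit2)) break
      fit <- fit2
    }
  }
  if (is.null(fit)) {                      # moment fallback
    w <- pmax(v1, 0)
    center <- sum(w * u) / sum(w)
    fit <- list(center = center,
                sd = sqrt(sum(w * (u - center)^2) / sum(w)))
  }
  # a center far outside the sampling window means the normal missed the peak
  if (!is.finite(fit$center) || fit$center < min(u) || fit$center > max(u)) {
    return(list(amp = amp, center = fit$center, sd = fit$sd,
                offset = offset, flagged = TRUE))
  }
  list(amp = amp, center = fit$center, sd = fit$sd, offset = offset,
       flagged = FALSE)
}

#' Width and peak intensity along the flagellum in every plane
#'
#' For each arc-length point and plane, the intensity is sampled along the
#' local normal (bilinear interpolation) and a 1D Gaussian is fitted,
#' yielding the flagellar width (Gaussian sd, um) and peak intensity.
#' Fit failures (no peak above the noise) are flagged per point.
#'
#' @param frame a [multifocal_frame()].
#' @param trace a `flagellum_trace` from [extract_centerline_2d()].
#' @param halfwidth_px half-length of the normal sampling window (default 12).
#' @param smooth_um arc-length window (um) of a median+mean smoothing applied
#'   to the measured widths and peaks (0 = off). Widths vary on the scale of
#'   the beat wavelength, so smoothing over ~2 um suppresses per-point fit
#'   noise without biasing the profile.
#' @return List of per-plane data frames with columns `s`, `width_um`,
#'   `peak`, `center_offset_px`, `flagged`.
#' @export
measure_width_profile <- function(frame, trace, halfwidth_px = 12,
                                  smooth_um = 2.2) {
  stopifnot(inherits(frame, "multifocal_frame"),
            inherits(trace, "flagellum_trace"))
  pts <- trace$points
  n <- nrow(pts)
  # tangents by central differences; normals perpendicular
  tx <- c(pts$x[2] - pts$x[1], (pts$x[3:n] - pts$x[1:(n - 2)]) / 2,
          pts$x[n] - pts$x[n - 1])
  ty <- c(pts$y[2] - pts$y[1], (pts$y[3:n] - pts$y[1:(n - 2)]) / 2,
          pts$y[n] - pts$y[n - 1])
  tl <- sqrt(tx^2 + ty^2)
  nxv <- -ty / tl; nyv <- tx / tl
  u <- seq(-halfwidth_px, halfwidth_px, by = 1)
  nu <- length(u)
  # one bilinear gather per plane: all normals sampled at once
  sx <- rep(pts$x, each = nu) + rep(u, n) * rep(nxv, each = nu)
  sy <- rep(pts$y, each = nu) + rep(u, n) * rep(nyv, each = nu)
  lapply(seq_along(frame$planes), function(k) {
    vall <- matrix(bilinear_sample(frame$planes[[k]], sx, sy), nrow = nu)
    width <- peak <- ctr <- rep(NA_real_, n)
    flagged <- rep(TRUE, n)
    for (i in seq_len(n)) {
      v <- vall[, i]
      ok <- !is.na(v)
      if (sum(ok) < 5) next
      f <- gauss_profile_fit(u[ok], v[ok])
      width[i] <- f$sd * trace$pixel_pitch
      peak[i] <- if (f$flagged) f$amp else f$amp + f$offset
      ctr[i] <- f$center
      flagged[i] <- f$flagged
    }
    out <- data.frame(s = pts$s, width_um = width, peak = peak,
                      center_offset_px = ctr, flagged = flagged)
    if (smooth_um > 0 && nrow(out) > 2) {
      pitch_s <- stats::median(diff(out$s))
      out$width_um <- smooth_arclength(out$width_um, pitch_s, smooth_um)
      out$peak <- smooth_arclength(out$peak, pitch_s, smooth_um)
    }
    out
  })
}

#' Flagellar width calibration map
#'
#' Accumulates width measurements of immotile cells swept through z into a
#' per-plane map of width as a function of arc length and z-distance to the
#' plane, averages across cells, and smooths each map with a 6 x 6 median
#' filter.
#'
#' @param cells list, one element per calibration cell, each a list with
#'   `s` (arc-length grid, um), `piezo_z` (um) and `width` (array
#'   `n_z x n_s x n_planes` of widths in um).
#' @param plane_offsets focal offsets of the planes (um); converts piezo
#'   position to per-plane z-distance.
#' @param median_w median-filter kernel width (default 6).
#' @return Object of class `width_calibration`: `s`, `dz` (z-distance grid),
#'   and `maps` (list per plane of `n_dz x n_s` matrices).
#' @export
build_width_calibration <- function(cells, plane_offsets, median_w = 6L) {
  stopifnot(length(cells) >= 1)
  s_grid <- cells[[1]]$s
  z_grid <- cells[[1]]$piezo_z
  n_planes <- dim(cells[[1]]$width)[3]
  acc <- array(0, c(length(z_grid), length(s_grid), n_planes))
  cnt <- array(0, dim(acc))
  for (cell in cells) {
    w <- cell$width
    if (!identical(cell$s, s_grid)) {
      # regrid arc length by linear interpolation
      w2 <- array(NA_real_, c(dim(w)[1], length(s_grid), n_planes))
      for (k in seq_len(n_planes)) for (iz in seq_len(dim(w)[1])) {
        w2[iz, , k] <- stats::approx(cell$s, w[iz, , k], s_grid, rule = 1)$y
      }
      w <- w2
    }
    if (!isTRUE(all.equal(cell$piezo_z, z_grid)))
      stop("calibration cells must share the piezo grid")
    ok <- is.finite(w)
    acc[ok] <- acc[ok] + w[ok]
    cnt <- cnt + ok
  }
  if (all(cnt == 0)) stop("empty overlap between calibration cells")
  avg <- acc / pmax(cnt, 1)
  avg[cnt == 0] <- NA_real_
  maps <- lapply(seq_len(n_planes), function(k) {
    m <- avg[, , k]
    m[!is.finite(m)] <- stats::median(m, na.rm = TRUE)
    median_filter2d(m, median_w)
  })
  # propagated depth precision per map cell: across-cell width spread (a
  # noise-scale fallback when only one cell is available) over the local
  # width-vs-dz slope
  dz_step <- stats::median(diff(z_grid))
  sw <- if (length(cells) > 1) {
    arr <- array(NA_real_, c(dim(acc), length(cells)))
    # recompute spread: cheap second pass over cells on the common grid
    for (ci in seq_along(cells)) {
      w <- cells[[ci]]$width
      if (!identical(cells[[ci]]$s, s_grid)) {
        w2 <- array(NA_real_, c(dim(w)[1], length(s_grid), n_planes))
        for (k in seq_len(n_planes)) for (iz in seq_len(dim(w)[1])) {
          w2[iz, , k] <- stats::approx(cells[[ci]]$s, w[iz, , k], s_grid,
                                       rule = 1)$y
        }
        w <- w2
      }
      arr[, , , ci] <- w
    }
    apply(arr, c(1, 2, 3), function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) stats::sd(v) else NA_real_
    })
  } else NULL
  sigma_z_maps <- lapply(seq_len(n_planes), function(k) {
    slope <- apply(maps[[k]], 2, sg_slope,
                   w = max(5L, 2L * floor(1 / abs(dz_step) / 2) + 1L),
                   dx = dz_step)
    spread <- if (!is.null(sw)) {
      sp <- sw[, , k]
      sp[!is.finite(sp)] <- stats::median(sp, na.rm = TRUE)
      sp
    } else 0.02  # um, conservative width repeatability for a single cell
    out <- abs(spread / slope)
    out[!is.finite(out)] <- Inf
    out
  })
  structure(list(s = s_grid,
                 dz = lapply(plane_offsets, function(off) z_grid - off),
                 plane_offsets = plane_offsets, maps = maps,
                 sigma_z_maps = sigma_z_maps),
            class = "width_calibration")
}

# Two candidate z-distances (one per side of focus) from inverting a width
# map column; delegates to the same monotone-branch inversion used for the
# bead radius curves. Widths below the map minimum return the minimum's
# position, flagged; widths above a branch maximum return the flagged
# boundary.
#' @noRd
invert_width_column <- function(dz, wcol, w_meas) {
  ok <- is.finite(wcol)
  dz <- dz[ok]; wcol <- wcol[ok]
  if (length(dz) < 2) return(structure(numeric(0), flagged = TRUE))
  below <- w_meas < min(wcol)
  cands <- difference_minima(dz, wcol, w_meas)
  structure(as.numeric(cands), boundary = attr(cands, "boundary"),
            flagged = below || any(attr(cands, "boundary")))
}

#' Width-based z-inference along the flagellum
#'
#' Per arc-length point and plane, the measured width is inverted through the
#' calibration map into two candidate z-positions (one above and one below
#' that plane's focus); the candidates are resolved across planes with the
#' same precision-weighted two-minima machinery used for beads
#' ([infer_bead_z()]).
#'
#' @param widths per-plane width measurements from [measure_width_profile()].
#' @param calib a [build_width_calibration()] result.
#' @return Data frame with `s`, `z` (um, absolute: plane offsets included),
#'   `n_planes`, `flagged`.
#' @export
infer_flagellar_z <- function(widths, calib) {
  stopifnot(inherits(calib, "width_calibration"))
  n_planes <- length(calib$maps)
  s_pts <- widths[[1]]$s
  rows <- lapply(seq_along(s_pts), function(i) {
    s <- s_pts[i]
    js <- which.min(abs(calib$s - s))
    cands <- list(); used <- integer(0); fl <- FALSE
    for (k in seq_len(n_planes)) {
      wi <- widths[[k]]
      if (i > nrow(wi) || wi$flagged[i] || !is.finite(wi$width_um[i])) next
      cv <- invert_width_column(calib$dz[[k]], calib$maps[[k]][, js],
                                wi$width_um[i])
      if (!length(cv)) next
      if (isTRUE(attr(cv, "flagged"))) fl <- TRUE
      # convert plane-relative distance to absolute z
      bd <- attr(cv, "boundary")
      if (is.null(bd)) bd <- rep(FALSE, length(cv))
      cands[[length(cands) + 1]] <-
        structure(as.numeric(cv) + calib$plane_offsets[k], boundary = bd)
      used <- c(used, k)
    }
    if (length(cands) < 2) {
      return(data.frame(s = s, z = NA_real_, n_planes = length(cands),
                        flagged = TRUE))
    }
    sig_fun <- function(ii, zz) {
      k <- used[ii]
      stats::approx(calib$dz[[k]] + calib$plane_offsets[k],
                    calib$sigma_z_maps[[k]][, js], zz, rule = 2)$y
    }
    rc <- resolve_z_combination(cands, sig_fun)
    best <- rc$best[1]
    data.frame(s = s, z = unname(rc$score["mean", best]),
               n_planes = length(cands), flagged = fl)
  })
  do.call(rbind, rows)
}

#' Intensity-based z-inference along the flagellum
#'
#' Per point, the four (plane offset, peak intensity) pairs are fitted with a
#' Gaussian (log-parabola solve); the center is the z-position. Degenerate or
#' monotone profiles (center outside the plane span) are flagged and excluded
#' from fusion.
#'
#' @param widths per-plane measurements from [measure_width_profile()] (the
#'   `peak` column is used).
#' @param plane_offsets focal offsets (um).
#' @param margin_um how far outside the plane span a center may fall before
#'   it is flagged unreliable (default 1.5 um).
#' @return Data frame with `s`, `z`, `flagged`.
#' @export
infer_z_from_intensity <- function(widths, plane_offsets, margin_um = 1.5) {
  s_pts <- widths[[1]]$s
  span <- range(plane_offsets)
  rows <- lapply(seq_along(s_pts), function(i) {
    peak <- vapply(widths, function(wi) wi$peak[i], numeric(1))
    ok <- is.finite(peak) & peak > 0
    if (sum(ok) < 3) {
      return(data.frame(s = s_pts[i], z = NA_real_, flagged = TRUE))
    }
    co <- stats::coef(stats::lm(log(peak[ok]) ~ plane_offsets[ok] +
                                  I(plane_offsets[ok]^2)))
    if (!is.finite(co[3]) || co[3] >= 0) {
      return(data.frame(s = s_pts[i], z = NA_real_, flagged = TRUE))
    }
    z <- -co[2] / (2 * co[3])
    out_of_span <- z < span[1] - margin_um || z > span[2] + margin_um
    data.frame(s = s_pts[i], z = z, flagged = out_of_span)
  })
  do.call(rbind, rows)
}

#' Smooth z-profiles along the arc length
#'
#' Centered moving median followed by a moving average, with shrinking
#' windows at the endpoints. Accepts a vector (one timepoint) or a matrix
#' (timepoints x arc positions, smoothed row-wise).
#'
#' @param z numeric vector or matrix of z-positions (um).
#' @param pitch_um arc-length pitch of the samples.
#' @param window_um smoothing window (default 2.2 um, about 7 samples at the
#'   standard pitch).
#' @return Smoothed object of the same shape.
#' @export
smooth_arclength <- function(z, pitch_um = 11 / 32, window_um = 2.2) {
  w <- max(1L, 2L * floor(window_um / pitch_um / 2) + 1L)
  smooth1 <- function(v) moving_average(moving_median(v, w), w)
  if (is.matrix(z)) t(apply(z, 1, smooth1)) else smooth1(z)
}

#' Reconstruct a flagellar time series in 3D
#'
#' Runs [trace_flagellum_3d()] on every frame, resamples all timepoints onto
#' the common arc-length grid of the shortest trace, and applies a mild
#' temporal smoothing of z (centered moving median then mean over
#' `t_window` frames; 3 frames attenuate a 25-Hz beat sampled at 500 fps by
#' ~3% while averaging uncorrelated per-frame noise).
#'
#' @param frames list of [multifocal_frame()]s.
#' @param calib a [build_width_calibration()] result.
#' @param t_window temporal smoothing window in frames (odd; 1 = off).
#' @param ... passed to [trace_flagellum_3d()].
#' @return List with `s` (um), `t` (s), and `x`, `y`, `z` matrices
#'   (timepoints x arc positions, um).
#' @export
reconstruct_beat <- function(frames, calib, t_window = 3L, ...) {
  traces <- lapply(frames, function(fr) {
    tryCatch(trace_flagellum_3d(fr, calib, ...), error = function(e) NULL)
  })
  ok <- !vapply(traces, is.null, logical(1))
  traces <- traces[ok]
  if (!length(traces)) stop("no frame could be reconstructed")
  s_max <- min(vapply(traces, function(tr) max(tr$s), numeric(1)))
  s_grid <- seq(0, s_max, by = stats::median(diff(traces[[1]]$s)))
  res <- lapply(c("x", "y", "z"), function(fld) {
    do.call(rbind, lapply(traces, function(tr) {
      stats::approx(tr$s, tr[[fld]], s_grid, rule = 2)$y
    }))
  })
  names(res) <- c("x", "y", "z")
  if (t_window > 1 && nrow(res$z) > t_window) {
    for (fld in c("x", "y", "z")) {
      res[[fld]] <- apply(res[[fld]], 2, function(col) {
        moving_average(moving_median(col, t_window), t_window)
      })
    }
  }
  list(s = s_grid,
       t = vapply(frames[ok], function(fr) fr$timestamp, numeric(1)),
       x = res$x, y = res$y, z = res$z)
}

#' Full 3D reconstruction of one multifocal frame
#'
#' Convenience pipeline: select the sharpest plane, trace the 2D centerline,
#' measure per-plane widths and intensities, infer z by the width and
#' intensity routes, fuse (unweighted mean of unflagged estimates) and smooth
#' along the arc length. Points at arc length below `head_um` keep their
#' values but are flagged lower-confidence.
#'
#' @param frame a [multifocal_frame()].
#' @param calib a [build_width_calibration()] result.
#' @param fuse one of "width", "intensity", "both".
#' @param head_um low-confidence head/midpiece region (default 10 um).
#' @param ... passed to [extract_centerline_2d()].
#' @return Data frame with `s`, `x`, `y` (um), `z` (um), `z_width`,
#'   `z_intensity`, `low_confidence`.
#' @export
trace_flagellum_3d <- function(frame, calib, fuse = "width", head_um = 10,
                               ...) {
  trace <- extract_centerline_2d(
    frame$planes[[select_sharpest_plane(frame)]],
    pixel_pitch = frame$pixel_pitch, ...)
  widths <- measure_width_profile(frame, trace)
  zw <- infer_flagellar_z(widths, calib)
  zi <- infer_z_from_intensity(widths, calib$plane_offsets)
  z <- switch(fuse,
              width = zw$z,
              intensity = ifelse(zi$flagged, NA_real_, zi$z),
              both = rowMeans(cbind(ifelse(zw$flagged, NA, zw$z),
                                    ifelse(zi$flagged, NA, zi$z)),
                              na.rm = TRUE))
  z[is.nan(z)] <- NA_real_
  # fill isolated gaps before smoothing
  if (anyNA(z) && any(!is.na(z))) {
    z <- stats::approx(trace$points$s[!is.na(z)], z[!is.na(z)],
                       trace$points$s, rule = 2)$y
  }
  data.frame(s = trace$points$s,
             x = trace$points$x * frame$pixel_pitch,
             y = trace$points$y * frame$pixel_pitch,
             z = smooth_arclength(z),
             z_width = zw$z, z_intensity = zi$z,
             low_confidence = trace$points$s < head_um)
}
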