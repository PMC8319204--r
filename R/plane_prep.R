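# Plane preparation: intensity normalization, grid-based registration,
# interplane distances, EDOF/depth maps.

#' Build a per-plane fractional intensity map from a blank recording
#'
#' The four split light paths do not deliver identical intensity. From a
#' frame recorded without a specimen, each plane is smoothed and divided by
#' the global mean over all planes, giving the fractional intensity each
#' pixel receives.
#'
#' @param blank_frame a [multifocal_frame()] recorded without a specimen.
#' @param smooth_sigma_px Gaussian smoothing applied before taking ratios
#'   (suppresses pixel noise; default 4 px).
#' @return Object of class `intensity_map`: list of per-plane matrices of
#'   fractional intensity (> 0, mean ~ 1 over all planes).
#' @export
build_intensity_map <- function(blank_frame, smooth_sigma_px = 4) {
  stopifnot(inherits(blank_frame, "multifocal_frame"))
  sm <- lapply(blank_frame$planes, gaussian_blur, sigma = smooth_sigma_px)
  g <- mean(unlist(lapply(sm, mean)))
  if (g <= 0) stop("invalid blank frame: non-positive mean intensity")
  maps <- lapply(sm, function(p) p / g)
  if (any(vapply(maps, function(m) any(m <= 0), logical(1))))
    stop("invalid intensity map: non-positive fractional values")
  structure(maps, class = "intensity_map")
}

#' Normalize plane intensities with a fractional intensity map
#'
#' Each pixel is divided by its fractional intensity value, flattening the
#' illumination/splitting profile. Linear: `normalize(a * I) = a *
#' normalize(I)`.
#'
#' @param frame a [multifocal_frame()].
#' @param map an `intensity_map` from [build_intensity_map()].
#' @return The normalized [multifocal_frame()].
#' @export
normalize_planes <- function(frame, map) {
  stopifnot(inherits(frame, "multifocal_frame"), inherits(map, "intensity_map"),
            length(map) == length(frame$planes))
  if (any(vapply(map, function(m) any(!is.finite(m) | m <= 0), logical(1))))
    stop("invalid intensity map: values must be finite and > 0")
  frame$planes <- Map(function(p, m) p / m, frame$planes, unclass(map))
  frame
}

#' Per-plane similarity registration model
#'
#' Plane 1 is the reference (identity). Each other plane carries a similarity
#' transform (isotropic scale + translation, optional rotation) mapping its
#' coordinates into plane-1 coordinates:
#' `p1 = scale * R(theta) * p_k + shift`.
#'
#' @param transforms list with elements `scale`, `theta`, `tx`, `ty` per
#'   plane.
#' @param residual_px mean skeleton distance after alignment, per plane.
#' @return Object of class `registration_model`.
#' @export
registration_model <- function(transforms, residual_px = NULL) {
  structure(list(transforms = transforms, residual_px = residual_px),
            class = "registration_model")
}

#' @noRd
identity_transform <- function() list(scale = 1, theta = 0, tx = 0, ty = 0)

#' @noRd
apply_similarity <- function(xy, tr) {
  ct <- cos(tr$theta); st <- sin(tr$theta)
  cbind(tr$scale * (ct * xy[, 1] - st * xy[, 2]) + tr$tx,
        tr$scale * (st * xy[, 1] + ct * xy[, 2]) + tr$ty)
}

# Point-to-line similarity fit: minimizes only the normal components
# n_i . (s R p_i + t - m_i), a linear LS in (s, tx, ty) and, with rotation,
# a small-angle theta. Tangential components along grid lines carry no
# information and would otherwise shrink the scale estimate.
#' @noRd
fit_similarity_normal <- function(src, matched, normals, rotation = FALSE) {
  nx <- normals[, 1]; ny <- normals[, 2]
  b <- nx * matched[, 1] + ny * matched[, 2]
  A <- cbind(nx * src[, 1] + ny * src[, 2], nx, ny)
  if (rotation) A <- cbind(A, nx * (-src[, 2]) + ny * src[, 1])
  cf <- qr.coef(qr(A), b)
  theta <- if (rotation) atan2(cf[4], cf[1]) else 0
  scale <- if (rotation) sqrt(cf[1]^2 + cf[4]^2) else cf[1]
  list(scale = unname(scale), theta = unname(theta),
       tx = unname(cf[2]), ty = unname(cf[3]))
}

# Closed-form similarity fit (Umeyama/Procrustes): maps src -> dst.
#' @noRd
fit_similarity <- function(src, dst, rotation = FALSE) {
  ms <- colMeans(src); md <- colMeans(dst)
  s0 <- sweep(src, 2, ms); d0 <- sweep(dst, 2, md)
  if (rotation) {
    H <- crossprod(s0, d0)
    sv <- svd(H)
    R <- sv$v %*% t(sv$u)
    if (det(R) < 0) {
      sv$v[, 2] <- -sv$v[, 2]
      R <- sv$v %*% t(sv$u)
    }
    theta <- atan2(R[2, 1], R[1, 1])
    scale <- sum(diag(t(d0) %*% s0 %*% t(R))) / sum(s0^2)
  } else {
    theta <- 0
    scale <- sum(s0 * d0) / sum(s0^2)
  }
  ct <- cos(theta); st <- sin(theta)
  rot_ms <- c(ct * ms[1] - st * ms[2], st * ms[1] + ct * ms[2])
  list(scale = scale, theta = theta,
       tx = md[1] - scale * rot_ms[1], ty = md[2] - scale * rot_ms[2])
}

#' Register planes from a calibration-grid frame
#'
#' Each plane is segmented with Li's minimum-cross-entropy threshold,
#' skeletonized, and the skeleton point set is aligned to plane 1 by an
#' ICP-style iteration (nearest-neighbour matching + closed-form similarity
#' fit; max 20 iterations, convergence below 0.01 px mean shift).
#'
#' @param grid_frame a [multifocal_frame()] showing the calibration grid in
#'   all planes.
#' @param rotation logical; also estimate a rotation (default FALSE: the
#'   model corrects shifts and minute magnification differences only).
#' @param max_iter,tol_px ICP iteration controls.
#' @return A [registration_model()] with per-plane residual mean skeleton
#'   distance (px).
#' @export
register_planes_from_grid <- function(grid_frame, rotation = FALSE,
                                      max_iter = 20L, tol_px = 0.01) {
  stopifnot(inherits(grid_frame, "multifocal_frame"))
  skels <- lapply(grid_frame$planes, function(p) {
    mask <- p > li_threshold(p)
    if (!any(mask)) stop("registration failure: empty segmentation in a plane")
    sk <- skeletonize_zs(mask)
    idx <- which(sk, arr.ind = TRUE)
    pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)  # 0-based pixel coords
    # drop border points: clipped structures bias the centroid refinement
    # and the similarity fit
    b <- 8
    pts <- pts[pts[, 1] >= b & pts[, 1] < ncol(p) - b &
                 pts[, 2] >= b & pts[, 2] < nrow(p) - b, , drop = FALSE]
    if (!nrow(pts)) stop("registration failure: empty segmentation in a plane")
    # refine to subpixel by mean-shift toward the intensity^2 ridge crest.
    # The window is re-centered on the *fractional* current estimate and
    # sampled bilinearly: a window anchored at a fixed integer pixel has a
    # pixel-locked fixed point that biases fractional crest positions.
    sm <- gaussian_blur(p, 1)
    r <- 4L
    offs <- expand.grid(dx = -r:r, dy = -r:r)
    pts <- apply(pts, 2, as.numeric)
    n_pts <- nrow(pts)
    for (it in 1:12) {
      sx <- rep(pts[, 1], each = nrow(offs)) + rep(offs$dx, n_pts)
      sy <- rep(pts[, 2], each = nrow(offs)) + rep(offs$dy, n_pts)
      w <- matrix(bilinear_sample(sm, sx, sy)^2, nrow = nrow(offs))
      w[is.na(w)] <- 0
      sw <- colSums(w)
      ok <- sw > 0
      mx <- colSums(w * offs$dx) / sw
      my <- colSums(w * offs$dy) / sw
      # clamp per-iteration motion to stay on this ridge
      pts[ok, 1] <- pts[ok, 1] + pmax(-1, pmin(1, mx[ok]))
      pts[ok, 2] <- pts[ok, 2] + pmax(-1, pmin(1, my[ok]))
    }
    colnames(pts) <- c("x", "y")
    pts
  })
  ref <- skels[[1]]
  # local structure normals of the reference skeleton (minor PCA axis of a
  # small neighbourhood); correspondences are projected onto them so that
  # the unobservable tangential component along a grid line cannot drag the
  # similarity fit (the ICP "aperture" bias shrinks scale estimates)
  kn <- min(9L, nrow(ref))
  nb <- FNN::get.knn(ref, k = kn - 1L)$nn.index
  ref_normal <- t(vapply(seq_len(nrow(ref)), function(i) {
    ngh <- ref[c(i, nb[i, ]), , drop = FALSE]
    e <- eigen(stats::cov(ngh), symmetric = TRUE)
    e$vectors[, 2]
  }, numeric(2)))
  n_planes <- length(skels)
  transforms <- vector("list", n_planes)
  residual <- numeric(n_planes)
  transforms[[1]] <- identity_transform()
  residual[1] <- 0
  for (k in seq_len(n_planes)[-1]) {
    tr <- identity_transform()
    pts <- skels[[k]]
    for (it in seq_len(max_iter)) {
      cur <- apply_similarity(pts, tr)
      nn <- FNN::get.knnx(ref, cur, k = 1)
      # trim poor matches (partial overlap at the field edges)
      keep <- nn$nn.dist[, 1] <= 3 * stats::median(nn$nn.dist[, 1]) + 1e-9
      idx <- nn$nn.index[keep, 1]
      matched <- ref[idx, , drop = FALSE]
      nrm <- ref_normal[idx, , drop = FALSE]
      tr_new <- fit_similarity_normal(pts[keep, , drop = FALSE], matched,
                                      nrm, rotation = rotation)
      shift <- mean(sqrt(rowSums((apply_similarity(pts, tr_new) - cur)^2)))
      tr <- tr_new
      if (shift < tol_px) break
    }
    cur <- apply_similarity(pts, tr)
    residual[k] <- mean(FNN::get.knnx(ref, cur, k = 1)$nn.dist[, 1])
    transforms[[k]] <- tr
  }
  registration_model(transforms, residual_px = residual)
}

#' Resample planes into plane-1 coordinates
#'
#' Bilinear resampling of each plane under its similarity transform. An exact
#' identity model is a no-op.
#'
#' @param frame a [multifocal_frame()].
#' @param model a [registration_model()] from the same optical configuration.
#' @return The aligned [multifocal_frame()].
#' @export
apply_registration <- function(frame, model) {
  stopifnot(inherits(frame, "multifocal_frame"),
            inherits(model, "registration_model"))
  if (length(model$transforms) != length(frame$planes))
    stop("registration model and frame have different plane counts")
  ny <- nrow(frame$planes[[1]]); nx <- ncol(frame$planes[[1]])
  grid <- cbind(x = rep(0:(nx - 1), each = ny), y = rep(0:(ny - 1), nx))
  frame$planes <- Map(function(p, tr) {
    if (tr$scale == 1 && tr$theta == 0 && tr$tx == 0 && tr$ty == 0) return(p)
    # output pixel (in plane-1 coords) samples the source at the inverse map
    ct <- cos(tr$theta); st <- sin(tr$theta)
    ux <- (grid[, 1] - tr$tx) / tr$scale
    uy <- (grid[, 2] - tr$ty) / tr$scale
    sx <- ct * ux + st * uy
    sy <- -st * ux + ct * uy
    v <- bilinear_sample(p, sx, sy)
    v[is.na(v)] <- 0
    matrix(v, ny, nx)
  }, frame$planes, model$transforms)
  frame
}

#' Estimate interplane distances from a focus sweep
#'
#' For each plane, the focus position is the piezo position maximizing the
#' standard deviation of pixel intensity, refined by a 3-point parabola
#' through the sharpness maximum. Offsets are reported relative to plane 1.
#'
#' @param zstack list of [multifocal_frame()]s, one per piezo position.
#' @param piezo_z strictly monotonic piezo positions (um), one per frame.
#' @return Numeric vector of plane offsets (um); attribute `boundary` flags
#'   planes whose sharpness peak sits at the stack boundary.
#' @export
estimate_interplane_distances <- function(zstack, piezo_z) {
  stopifnot(length(zstack) == length(piezo_z), length(zstack) >= 1)
  d <- diff(piezo_z)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("piezo_z must be strictly monotonic")
  # order invariance: sort by piezo position
  ord <- order(piezo_z)
  piezo_z <- piezo_z[ord]; zstack <- zstack[ord]
  n_planes <- length(zstack[[1]]$planes)
  sharp <- vapply(zstack, function(fr) {
    vapply(fr$planes, stats::sd, numeric(1))
  }, numeric(n_planes))
  sharp <- matrix(sharp, nrow = n_planes)
  focus <- numeric(n_planes)
  boundary <- logical(n_planes)
  for (k in seq_len(n_planes)) {
    v <- sharp[k, ]
    i <- which.max(v)
    if (i == 1 || i == length(v)) {
      boundary[k] <- TRUE
      focus[k] <- piezo_z[i]
      if (length(v) > 1)
        warning("sharpness maximum at stack boundary for plane ", k,
                ": focus not bracketed")
    } else {
      # parabolic refinement over the top of the sharpness curve; a wide
      # fit window stabilizes the vertex when the peak is flat
      thr <- v[i] - 0.1 * (v[i] - min(v))
      jj <- i
      while (jj > 1 && v[jj - 1] >= thr) jj <- jj - 1
      kk <- i
      while (kk < length(v) && v[kk + 1] >= thr) kk <- kk + 1
      sel <- max(1, min(jj, i - 1)):min(length(v), max(kk, i + 1))
      xs <- piezo_z[sel]; ys <- v[sel]
      co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
      focus[k] <- if (is.finite(co[3]) && co[3] < 0 &&
                      -co[2] / (2 * co[3]) >= min(xs) &&
                      -co[2] / (2 * co[3]) <= max(xs))
        -co[2] / (2 * co[3]) else piezo_z[i]
    }
  }
  structure(focus - focus[1], boundary = boundary)
}

#' Extended depth-of-field composite and max-variance depth map
#'
#' Sharpness is the local intensity variance in a `window_px` window. The
#' depth map holds, per pixel, the index of the sharpest plane (ties break to
#' the lowest index); the EDOF image takes each pixel from that plane.
#'
#' @param frame a [multifocal_frame()].
#' @param window_px odd window size >= 3 (default 9).
#' @param median_px optional odd width of a median filter applied to the
#'   depth map (0 = off, the default).
#' @return List with `edof` (matrix) and `depth` (integer matrix of plane
#'   indices).
#' @export
edof_depth_map <- function(frame, window_px = 9L, median_px = 0L) {
  stopifnot(inherits(frame, "multifocal_frame"),
            window_px >= 3, window_px %% 2 == 1)
  vars <- lapply(frame$planes, local_variance, w = window_px)
  ny <- nrow(vars[[1]]); nx <- ncol(vars[[1]])
  depth <- matrix(1L, ny, nx)
  best <- vars[[1]]
  for (k in seq_along(vars)[-1]) {
    upd <- vars[[k]] > best            # strict: ties keep the lower index
    depth[upd] <- k
    best[upd] <- vars[[k]][upd]
  }
  if (median_px > 0) depth <- round(median_filter2d(depth, median_px))
  edof <- frame$planes[[1]]
  for (k in seq_along(frame$planes)[-1]) {
    sel <- depth == k
    edof[sel] <- frame$planes[[k]][sel]
  }
  list(edof = edof, depth = depth)
}
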