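# Kinematic descriptors of reconstructed 3D flagella.

#' Gyration-tensor nonplanarity of a flagellar shape
#'
#' The gyration tensor is the mean outer product of the centered 3D points.
#' With eigenvalues `l1 >= l2 >= l3`, the nonplanarity ratio is `l3 / l2`
#' (0 = perfectly planar, 1 = no preferential plane); the beat-plane normal
#' is the eigenvector of the smallest eigenvalue.
#'
#' @param points n x 3 matrix of flagellar points at one timepoint (n >= 4).
#' @return List with `ratio`, `normal` (unit length), `eigenvalues` (sorted
#'   decreasing, um^2), `degenerate` (TRUE for collinear input, where the
#'   ratio is undefined).
#' @export
nonplanarity <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 4)
  centered <- sweep(points, 2, colMeans(points))
  g <- crossprod(centered) / nrow(points)
  e <- eigen(g, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  degenerate <- ev[2] <= max(ev[1], .Machine$double.eps) * 1e-12
  ratio <- if (degenerate) NA_real_ else ev[3] / ev[2]
  normal <- e$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  list(ratio = ratio, normal = normal, eigenvalues = ev,
       degenerate = degenerate)
}

#' Rolling velocity from beat-plane normals
#'
#' Frame-to-frame signed rotation of the beat-plane normal about the
#' longitudinal (head-to-tail) axis, divided by the frame period. Positive
#' values mean clockwise rotation when viewing the sperm from head to tail.
#' Normals are sign-aligned between frames before measuring, since an
#' eigenvector's sign is arbitrary.
#'
#' @param normals n x 3 matrix of unit beat-plane normals over time.
#' @param dt frame period in s.
#' @param axis length-3 longitudinal reference axis (default +x).
#' @return List with `omega` (rad s^-1 series, length n-1), `mean_hz`
#'   (mean rotation frequency, omega / 2 pi), `ambiguous` (flags
#'   near-antiparallel consecutive normals).
#' @export
rolling_velocity <- function(normals, dt, axis = c(1, 0, 0)) {
  normals <- as.matrix(normals)
  stopifnot(ncol(normals) == 3, nrow(normals) >= 2, dt > 0)
  axis <- axis / sqrt(sum(axis^2))
  # project normals onto the plane orthogonal to the longitudinal axis
  proj <- normals - outer(drop(normals %*% axis), axis)
  # sign-align consecutive normals (eigenvectors have arbitrary sign)
  for (i in 2:nrow(proj)) {
    if (sum(proj[i, ] * proj[i - 1, ]) < 0) proj[i, ] <- -proj[i, ]
  }
  n <- nrow(proj)
  a <- proj[-n, , drop = FALSE]
  b <- proj[-1, , drop = FALSE]
  crossab <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                   a[, 3] * b[, 1] - a[, 1] * b[, 3],
                   a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sinth <- drop(crossab %*% axis)
  costh <- rowSums(a * b)
  theta <- atan2(sinth, costh)
  ambiguous <- sqrt(rowSums(a^2)) < 1e-9 | sqrt(rowSums(b^2)) < 1e-9 |
    abs(abs(theta) - pi) < 1e-6
  omega <- theta / dt
  list(omega = omega, mean_hz = mean(omega) / (2 * pi), ambiguous = ambiguous)
}

#' Taubin algebraic circle fit
#'
#' Gradient-weighted algebraic fit of a circle to 2D points (Taubin's
#' method): solves the generalized eigenproblem of the algebraic distance
#' under the Taubin normalization.
#'
#' @param xy n x 2 matrix of points.
#' @return List with `center` (length 2), `radius`.
#' @export
taubin_circle_fit <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  m <- colMeans(xy)
  x <- xy[, 1] - m[1]; y <- xy[, 2] - m[2]
  z <- x^2 + y^2
  zm <- mean(z)
  zr <- z - zm
  n <- nrow(xy)
  # Newton iteration on the characteristic polynomial (Taubin via moments)
  mxx <- mean(x^2); myy <- mean(y^2); mxy <- mean(x * y)
  mxz <- mean(x * z); myz <- mean(y * z); mzz <- mean(z^2)
  mz <- zm
  cov_xy <- mxx * myy - mxy^2
  a3 <- 4 * mz
  a2 <- -3 * mz^2 - mzz
  a1 <- mzz * mz + 4 * cov_xy * mz - mxz^2 - myz^2 - mz^3
  a0 <- mxz^2 * myy + myz^2 * mxx - mzz * cov_xy - 2 * mxz * myz * mxy +
    mz^2 * cov_xy
  xnew <- 0
  for (i in 1:50) {
    yold <- a0 + xnew * (a1 + xnew * (a2 + xnew * a3))
    dy <- a1 + xnew * (2 * a2 + xnew * 3 * a3)
    if (dy == 0) break
    xold <- xnew
    xnew <- xold - yold / dy
    if (abs((xnew - xold) / (abs(xnew) + 1e-30)) < 1e-12) break
  }
  A <- rbind(c(mxx - xnew, mxy), c(mxy, myy - xnew))
  bvec <- c(mxz / 2, myz / 2)
  sol <- tryCatch(solve(A, bvec), error = function(e) c(0, 0))
  center <- sol + m
  radius <- sqrt(sum(sol^2) + mz)
  list(center = center, radius = radius)
}

#' Signed 3D curvature field of a flagellar time series
#'
#' Per arc-length point and timepoint, the points inside a 4-um arc-length
#' window are projected onto their local osculating plane (the two major
#' gyration axes of the window) and Taubin's circle is fitted; the curvature
#' is 1/R with a sign that is kept continuous along s and t by propagating a
#' reference binormal orientation.
#'
#' @param frames list of n x 3 centerline matrices (one per timepoint).
#' @param s arc-length grid (um) shared by all frames.
#' @param window_um window length (default 4).
#' @return Matrix `kappa` (timepoints x arc positions, um^-1).
#' @export
signed_curvature <- function(frames, s, window_um = 4) {
  n_t <- length(frames)
  n_s <- length(s)
  half <- window_um / 2
  kap <- matrix(NA_real_, n_t, n_s)
  # per-arc-point binormal references for temporal sign continuity; only
  # confidently curved windows (|kappa| >= conf_k) may update them, so a
  # near-straight window's noise binormal cannot corrupt the propagation
  conf_k <- 0.01
  ref_s <- matrix(NA_real_, n_s, 3)
  for (ti in seq_len(n_t)) {
    pts <- frames[[ti]]
    prev_b <- NULL                     # s-propagation within the frame
    for (si in seq_len(n_s)) {
      idx <- which(s >= s[si] - half & s <= s[si] + half)
      if (length(idx) < 5) next
      w <- pts[idx, , drop = FALSE]
      cen <- colMeans(w)
      wc <- sweep(w, 2, cen)
      sv <- svd(wc, nu = 0, nv = 3)
      if (sv$d[2] < 1e-9) {           # straight segment
        kap[ti, si] <- 0
        next
      }
      e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
      p2 <- cbind(wc %*% e1, wc %*% e2)
      fit <- taubin_circle_fit(p2)
      k <- 1 / fit$radius
      if (!is.finite(k)) k <- 0
      # local binormal from the window's chords; kappa's sign follows the
      # binormal orientation, kept continuous in time at each arc point
      # (and along s within the first frame, which seeds the references)
      i0 <- 1L; i1 <- ceiling(length(idx) / 2); i2 <- length(idx)
      v1 <- w[i1, ] - w[i0, ]; v2 <- w[i2, ] - w[i1, ]
      bn <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      bl <- sqrt(sum(bn^2))
      if (bl <= 1e-12) {
        kap[ti, si] <- 0
        next
      }
      bn <- bn / bl
      ref <- if (all(is.finite(ref_s[si, ]))) ref_s[si, ]
        else if (!is.null(prev_b)) prev_b else bn
      if (sum(bn * ref) < 0) {
        bn <- -bn
        k <- -k
      }
      prev_b <- bn
      if (abs(k) >= conf_k) ref_s[si, ] <- bn
      kap[ti, si] <- k
    }
  }
  kap
}

#' Welch power spectral density
#'
#' Hann-tapered segments of `window` samples advanced by `step` samples
#' (default 200/40, i.e. 160-sample overlap); periodograms averaged. Falls
#' back to a single full-length periodogram (flagged) when the series is
#' shorter than one window.
#'
#' @param x numeric series (e.g. curvature at a fixed arc length over time).
#' @param frame_rate sampling rate in Hz.
#' @param window,step Welch segmentation in samples.
#' @return List with `freq` (Hz), `psd`, `peak_freq` (argmax above DC),
#'   `short_series` flag.
#' @export
power_spectrum <- function(x, frame_rate, window = 200L, step = 40L) {
  x <- as.numeric(x)
  n <- length(x)
  short <- n < window
  if (short) window <- n
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  starts <- seq(1L, n - window + 1L, by = step)
  u <- sum(taper^2)
  acc <- NULL
  for (s0 in starts) {
    seg <- x[s0:(s0 + window - 1L)]
    seg <- (seg - mean(seg)) * taper
    p <- abs(stats::fft(seg))^2 / (u * frame_rate)
    acc <- if (is.null(acc)) p else acc + p
  }
  psd <- acc / length(starts)
  nf <- floor(window / 2) + 1L
  psd <- psd[seq_len(nf)]
  if (window %% 2 == 0) {
    psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  } else {
    psd[2:nf] <- 2 * psd[2:nf]
  }
  freq <- (seq_len(nf) - 1L) * frame_rate / window
  peak <- freq[-1][which.max(psd[-1])]
  list(freq = freq, psd = psd, peak_freq = peak, short_series = short)
}

#' Harmonic decomposition of a curvature time course
#'
#' `C0` is the absolute mean; `C1` and `C2` are the discrete-Fourier cosine
#' amplitudes (`2 |X(f)| / N`) at the fundamental and its second harmonic.
#' The fundamental may be supplied or is estimated from the Welch peak.
#'
#' @param x curvature series at a fixed arc length (um^-1).
#' @param frame_rate sampling rate in Hz.
#' @param f0 fundamental frequency in Hz; NULL to estimate via
#'   [power_spectrum()].
#' @return List with `c0`, `c1`, `c2` (um^-1) and `f0` (Hz).
#' @export
harmonic_components <- function(x, frame_rate, f0 = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(f0)) {
    f0 <- power_spectrum(x, frame_rate)$peak_freq
  }
  if (!is.finite(f0) || f0 <= 0) stop("fundamental frequency not resolvable")
  if (n < 5 * frame_rate / f0)
    stop("series too short: need at least 5 beat cycles")
  tt <- (seq_len(n) - 1) / frame_rate
  amp_at <- function(f) {
    2 * Mod(sum((x - mean(x)) * exp(-2i * pi * f * tt))) / n
  }
  list(c0 = abs(mean(x)), c1 = amp_at(f0), c2 = amp_at(2 * f0), f0 = f0)
}

# Robust locally weighted linear regression (tricube kernel, bisquare
# robustification, 5 iterations) over a fixed time window.
#' @noRd
rlowess <- function(t, y, window_s, iterations = 5L) {
  n <- length(y)
  half <- window_s / 2
  rw <- rep(1, n)
  fitted <- y
  for (it in seq_len(iterations)) {
    fitted <- vapply(seq_len(n), function(i) {
      sel <- which(t >= t[i] - half & t <= t[i] + half)
      if (length(sel) < 2) return(y[i])
      d <- abs(t[sel] - t[i])
      dmax <- max(d, 1e-12)
      wt <- (1 - (d / dmax * 0.999)^3)^3 * rw[sel]
      if (sum(wt) <= 0) return(y[i])
      tc <- t[sel] - t[i]
      sw <- sum(wt); swx <- sum(wt * tc); swx2 <- sum(wt * tc^2)
      swy <- sum(wt * y[sel]); swxy <- sum(wt * tc * y[sel])
      den <- sw * swx2 - swx^2
      if (abs(den) < 1e-14) return(swy / sw)
      (swx2 * swy - swx * swxy) / den    # intercept at tc = 0
    }, numeric(1))
    res <- y - fitted
    s <- stats::median(abs(res))
    if (s <= 0) break
    rr <- res / (6 * s)
    rw <- ifelse(abs(rr) < 1, (1 - rr^2)^2, 0)
  }
  fitted
}

#' Swim speed from smoothed head trajectories
#'
#' Positions are smoothed by robust local linear regression with an 8-ms
#' window; a second 80-ms pass yields the trajectory centreline. The speed
#' is the 3D distance between consecutive centreline points divided by the
#' frame period.
#'
#' @param positions n x 3 matrix of head positions (um) over time.
#' @param frame_rate acquisition rate in Hz.
#' @param window_fast_s,window_slow_s the two smoothing windows (s).
#' @return List with `centreline` (n x 3), `speed` (um/s, length n-1),
#'   `mean_speed`.
#' @export
swim_speed <- function(positions, frame_rate, window_fast_s = 0.008,
                       window_slow_s = 0.080) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 3, frame_rate > 0)
  t <- (seq_len(nrow(positions)) - 1) / frame_rate
  sm <- apply(positions, 2, function(col) rlowess(t, col, window_fast_s))
  cl <- apply(sm, 2, function(col) rlowess(t, col, window_slow_s))
  d <- sqrt(rowSums(diff(cl)^2))
  speed <- d * frame_rate
  list(centreline = cl, speed = speed, mean_speed = mean(speed))
}
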