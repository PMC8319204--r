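# Low-level image operations on plain numeric matrices.
#
# Convention throughout the package: a plane image is a numeric matrix with
# rows indexing y (down) and columns indexing x (right). Pixel centers sit at
# integer coordinates in a 0-based system, i.e. matrix element [iy + 1, ix + 1]
# is the pixel centered at (x = ix, y = iy).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pad_replicate <- function(img, my, mx = my) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, my), seq_len(nr), rep(nr, my))
  ci <- c(rep(1L, mx), seq_len(nc), rep(nc, mx))
  img[ri, ci, drop = FALSE]
}

# 1D convolution of each column with kernel k (odd length), replicate padding.
#' @noRd
conv_cols <- function(img, k) {
  m <- (length(k) - 1L) / 2L
  p <- pad_replicate(img, my = m, mx = 0L)
  out <- matrix(0, nrow(img), ncol(img))
  # direct sum over kernel taps: O(len(k)) matrix adds, fast and exact
  for (i in seq_along(k)) {
    out <- out + k[i] * p[seq_len(nrow(img)) + (length(k) - i), , drop = FALSE]
  }
  out
}

#' @noRd
conv_rows <- function(img, k) t(conv_cols(t(img), k))

# Separable convolution, kernels given for x (rows direction of travel) and y.
#' @noRd
conv_sep <- function(img, kx, ky = kx) conv_rows(conv_cols(img, ky), kx)

#' @noRd
gauss_kernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Second derivative of a Gaussian; pairs with a plain Gaussian in the other
# axis to build a Laplacian-of-Gaussian response.
#' @noRd
gauss_d2_kernel <- function(sigma, radius = max(2L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  (x^2 / sigma^4 - 1 / sigma^2) * g
}

#' @noRd
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep(img, gauss_kernel(sigma))
}

# Scale-normalized negative LoG: bright blobs of radius ~ sigma*sqrt(2)
# give positive maxima.
#' @noRd
log_response <- function(img, sigma) {
  g <- gauss_kernel(sigma)
  d2 <- gauss_d2_kernel(sigma)
  lap <- conv_rows(conv_cols(img, g), d2) + conv_rows(conv_cols(img, d2), g)
  -sigma^2 * lap
}

# Box-filtered local mean via integral images; w odd window size.
#' @noRd
box_mean <- function(img, w) {
  m <- (w - 1L) / 2L
  p <- pad_replicate(img, m)
  s <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  nr <- nrow(img); nc <- ncol(img)
  i1 <- seq_len(nr); i2 <- i1 + 2L * m
  j1 <- seq_len(nc); j2 <- j1 + 2L * m
  (s[i2 + 1L, j2 + 1L, drop = FALSE] - s[i1, j2 + 1L, drop = FALSE] -
    s[i2 + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / w^2
}

# Local intensity variance in a w x w window (population variance).
#' @noRd
local_variance <- function(img, w) {
  mu <- box_mean(img, w)
  pmax(box_mean(img^2, w) - mu^2, 0)
}

# Li's minimum cross-entropy threshold (iterative form).
#' @noRd
li_threshold <- function(x, tol = 0.5e-3, max_iter = 100L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  # work on a shifted copy so logs are defined
  eps <- diff(rng) * 1e-6
  x0 <- x - rng[1] + eps
  t_new <- mean(x0)
  for (i in seq_len(max_iter)) {
    t_old <- t_new
    fg <- x0[x0 > t_old]; bg <- x0[x0 <= t_old]
    if (!length(fg) || !length(bg)) break
    mf <- mean(fg); mb <- mean(bg)
    t_new <- (mf - mb) / (log(mf) - log(mb))
    if (abs(t_new - t_old) < tol) break
  }
  t_new + rng[1] - eps
}

#' @noRd
shift_mat <- function(m, dy, dx, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# Zhang-Suen thinning of a logical mask to a 1-px skeleton.
#' @noRd
skeletonize_zs <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(img, -1, 0); p3 <- shift_mat(img, -1, 1)
      p4 <- shift_mat(img, 0, 1);  p5 <- shift_mat(img, 1, 1)
      p6 <- shift_mat(img, 1, 0);  p7 <- shift_mat(img, 1, -1)
      p8 <- shift_mat(img, 0, -1); p9 <- shift_mat(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0->1 transitions in the ordered neighbour ring
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- img == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# Bilinear interpolation at 0-based pixel coordinates (vectors x, y);
# out-of-range samples return NA.
#' @noRd
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp the upper neighbour so edge pixels interpolate against themselves
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    i00 <- cbind(y0[ok] + 1, x0[ok] + 1); i01 <- cbind(y0[ok] + 1, x1[ok] + 1)
    i10 <- cbind(y1[ok] + 1, x0[ok] + 1); i11 <- cbind(y1[ok] + 1, x1[ok] + 1)
    out[ok] <- img[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      img[i01] * fx[ok] * (1 - fy[ok]) +
      img[i10] * (1 - fx[ok]) * fy[ok] +
      img[i11] * fx[ok] * fy[ok]
  }
  out
}

# Local maxima of img: pixels equal to the max of a (2r+1)^2 neighbourhood.
# Returns a data.frame with 0-based ix, iy and the value.
#' @noRd
local_maxima <- function(img, radius = 1L) {
  mx <- img
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dy == 0 && dx == 0) next
    mx <- pmax(mx, shift_mat(img, dy, dx, fill = -Inf))
  }
  idx <- which(img >= mx & is.finite(img), arr.ind = TRUE)
  data.frame(ix = idx[, 2] - 1L, iy = idx[, 1] - 1L,
             value = img[idx])
}

# 2D quadratic sub-pixel refinement around a 0-based integer peak.
#' @noRd
subpixel_peak <- function(img, ix, iy) {
  nr <- nrow(img); nc <- ncol(img)
  r <- iy + 1L; c <- ix + 1L
  dx <- 0; dy <- 0
  if (c > 1 && c < nc) {
    den <- img[r, c - 1] - 2 * img[r, c] + img[r, c + 1]
    if (den < 0) dx <- 0.5 * (img[r, c - 1] - img[r, c + 1]) / den
  }
  if (r > 1 && r < nr) {
    den <- img[r - 1, c] - 2 * img[r, c] + img[r + 1, c]
    if (den < 0) dy <- 0.5 * (img[r - 1, c] - img[r + 1, c]) / den
  }
  c(x = ix + max(-0.5, min(0.5, dx)), y = iy + max(-0.5, min(0.5, dy)))
}

# 2D median filter with a w x w window (replicate padding). An even window
# has no central pixel; to avoid a half-pixel phase shift, the two
# complementary offset phases are averaged in each dimension.
#' @noRd
median_filter2d <- function(img, w) {
  nr <- nrow(img); nc <- ncol(img)
  pfull <- pad_replicate(img, w, w)
  med_phase <- function(my, mx) {
    stack <- array(NA_real_, dim = c(nr, nc, w * w))
    k <- 0L
    for (dy in seq_len(w) - 1L - my) for (dx in seq_len(w) - 1L - mx) {
      k <- k + 1L
      stack[, , k] <- pfull[w + dy + seq_len(nr), w + dx + seq_len(nc)]
    }
    apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  }
  m <- (w - 1L) %/% 2L
  if (w %% 2 == 1) return(med_phase(m, m))
  (med_phase(m, m) + med_phase(m + 1L, m) +
    med_phase(m, m + 1L) + med_phase(m + 1L, m + 1L)) / 4
}

# Moving average along a vector with shrinking windows at the ends.
#' @noRd
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n < 2) return(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    mean(x[j], na.rm = TRUE)
  }, numeric(1))
}

# Local linear slope (Savitzky-Golay, order 1) with shrinking end windows.
#' @noRd
sg_slope <- function(x, w, dx = 1) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    if (length(j) < 2) return(NA_real_)
    u <- j - mean(j)
    sum(u * x[j]) / sum(u^2) / dx
  }, numeric(1))
}

#' @noRd
moving_median <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n < 2) return(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    stats::median(x[j], na.rm = TRUE)
  }, numeric(1))
}

# Evaluate a function under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
#' @noRd
with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}
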