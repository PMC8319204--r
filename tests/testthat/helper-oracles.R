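# Independent oracles used to cross-check package implementations.
# These deliberately avoid the code paths they verify.

# Brute-force weighted least squares for the linearized circle equation:
# normal equations solved with base solve(), independent of the qr path.
oracle_circle_wls <- function(x, y, I) {
  A <- cbind(2 * x, 2 * y, 1) * I^2
  B <- (x^2 + y^2) * I^2
  cf <- solve(t(A) %*% A, t(A) %*% B)
  r <- sqrt(cf[1]^2 + cf[2]^2 + cf[3])
  list(xc = cf[1], yc = cf[2], b = cf[3], radius = r)
}

# Direct gyration-tensor eigen solve (explicit 3x3 moment matrix).
oracle_gyration <- function(points) {
  c0 <- sweep(points, 2, colMeans(points))
  g <- matrix(0, 3, 3)
  for (i in seq_len(nrow(c0))) g <- g + c0[i, ] %o% c0[i, ]
  g <- g / nrow(c0)
  ev <- sort(eigen(g, symmetric = TRUE)$values, decreasing = TRUE)
  list(eigenvalues = ev, ratio = ev[3] / ev[2])
}

# Stokeslet: flow of a point force F (units so that |v| = |F| / (8 pi mu r)
# with mu = 1) at positions r relative to the force location.
oracle_stokeslet <- function(pos, force, mu = 1) {
  t(apply(pos, 1, function(r) {
    rn <- sqrt(sum(r^2))
    (force / rn + r * sum(force * r) / rn^3) / (8 * pi * mu)
  }))
}

# Exact two-lens ray-transfer-matrix focal shift for a thin lens f (mm) at
# distance d (mm) before the image plane: finds the object-side plane that
# images onto the chip by solving for vanishing B element.
oracle_thin_lens_shift <- function(f, d) {
  if (!is.finite(f)) return(0)
  # system from a plane at distance s before the lens to the chip:
  # M = T(d) L(f) T(s); imaging when B = d + s - d*s/f = 0
  s <- stats::uniroot(function(s) d + s - d * s / f,
                      interval = c(-1e7, 1e7), tol = 1e-10)$root
  # aerial-image displacement relative to the lens-free path (s = -d)
  s - (-d)
}

# Numerical radial convolution of a uniform disc with the transverse PSF
# exp(-r^2 / w^2) by direct polar quadrature, then the intensity-squared-
# weighted rms radius within the fit patch — the statistic the algebraic
# circle fit measures for a radially symmetric blob. Fully independent of
# the renderer (no pixel grid, no separable shortcut).
oracle_bead_rms_radius <- function(z_offset, psf, bead_radius_um,
                                   pitch_um, patch_radius_px = 10) {
  w <- psf_width(z_offset, psf)
  a <- bead_radius_um
  rho <- seq(0, patch_radius_px * pitch_um, length.out = 400)
  rp <- seq(0, a, length.out = 60)
  phi <- seq(0, 2 * pi, length.out = 120)
  prof <- vapply(rho, function(r0) {
    # I(r0) = int_0^a r' dr' int dphi exp(-(r0^2 + r'^2 - 2 r0 r' cos)/w^2)
    integ <- outer(rp, phi, function(r1, ph) {
      r1 * exp(-(r0^2 + r1^2 - 2 * r0 * r1 * cos(ph)) / w^2)
    })
    sum(integ) * (rp[2] - rp[1]) * (phi[2] - phi[1])
  }, numeric(1))
  # row-scaling the linear system by I^2 makes the effective LS weight I^4
  w2 <- prof^4 * rho                    # polar area element included
  sqrt(sum(w2 * rho^2) / sum(w2)) / pitch_um   # rms radius in px
}

# Curvature of a circular helix x = a cos t, y = a sin t, z = b t.
oracle_helix_curvature <- function(a, b) a / (a^2 + b^2)

# Unit helix point set.
make_helix <- function(a = 5, b = 1, turns = 2, n = 200) {
  t <- seq(0, turns * 2 * pi, length.out = n)
  cbind(a * cos(t), a * sin(t), b * t)
}

rot3 <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
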