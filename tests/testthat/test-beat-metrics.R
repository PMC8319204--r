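test_that("nonplanarity matches direct eigen analysis and its limits", {
  # planar points -> ratio 0
  th <- seq(0, 4 * pi, length.out = 100)
  planar <- cbind(5 * cos(th), 5 * sin(th), 0)
  expect_equal(nonplanarity(planar)$ratio, 0, tolerance = 1e-12)
  # near-uniform sphere surface -> ratio near 1
  set.seed(2)
  v <- matrix(rnorm(3 * 4000), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  expect_gt(nonplanarity(v)$ratio, 0.9)
  # helix vs brute-force gyration eigen solve
  hx <- make_helix(a = 5, b = 4 / (2 * pi), turns = 2, n = 300)
  got <- nonplanarity(hx)
  want <- oracle_gyration(hx)
  expect_equal(got$ratio, want$ratio, tolerance = 1e-9)
  expect_equal(got$eigenvalues, want$eigenvalues, tolerance = 1e-9)
  # collinear input is degenerate
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_true(nonplanarity(line)$degenerate)
  # invariance under rigid rotation + translation
  set.seed(3)
  for (i in 1:5) {
    R <- rot3(runif(1, 0, pi), runif(1, 0, pi), runif(1, 0, pi))
    moved <- sweep(hx %*% t(R), 2, runif(3, -20, 20), `+`)
    expect_equal(nonplanarity(moved)$ratio, got$ratio, tolerance = 1e-9)
  }
})

test_that("rolling velocity measures signed plane rotation", {
  n <- 200; dt <- 1 / 500
  # static plane -> zero
  still <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
  expect_equal(rolling_velocity(still, dt)$omega, rep(0, n - 1))
  # normal rotating at 21.362 rad/s about +x -> mean 3.4 Hz within 1%
  om <- 2 * pi * 3.4
  th <- om * (0:(n - 1)) * dt
  normals <- cbind(0, cos(th), sin(th))
  rv <- rolling_velocity(normals, dt, axis = c(1, 0, 0))
  expect_lt(abs(rv$mean_hz / 3.4 - 1), 0.01)
  expect_lt(abs(mean(rv$omega) / 21.362 - 1), 0.01)
  # reversing the rotation flips the sign
  rv2 <- rolling_velocity(normals[n:1, ], dt, axis = c(1, 0, 0))
  expect_equal(rv2$mean_hz, -rv$mean_hz, tolerance = 1e-9)
})

test_that("Taubin curvature is exact on circles and helices", {
  # planar circle radius 10 -> kappa = 0.100 everywhere
  th <- seq(0, 2 * pi, length.out = 400)
  s <- seq(0, 2 * pi * 10, length.out = 400)
  circ <- list(cbind(10 * cos(th), 10 * sin(th), 0))
  kap <- signed_curvature(circ, s)
  inner <- is.finite(kap[1, ])
  expect_equal(abs(kap[1, inner]), rep(0.1, sum(inner)), tolerance = 1e-6)
  # straight filament -> kappa = 0
  line <- list(cbind(seq(0, 50, length.out = 150), 0, 0))
  k0 <- signed_curvature(line, seq(0, 50, length.out = 150))
  expect_true(all(abs(k0[1, is.finite(k0[1, ])]) < 1e-9))
  # helix: kappa = a / (a^2 + b^2) within 2% on 4-um windows
  a <- 5; b <- 1
  tt <- seq(0, 4 * pi, length.out = 600)
  hx <- cbind(a * cos(tt), a * sin(tt), b * tt)
  s_hx <- sqrt(a^2 + b^2) * tt
  kh <- signed_curvature(list(hx), s_hx)
  want <- oracle_helix_curvature(a, b)
  mid <- s_hx > 4 & s_hx < max(s_hx) - 4
  expect_lt(max(abs(abs(kh[1, mid]) - want) / want, na.rm = TRUE), 0.02)
  # frame invariance: a rigidly rotated curve has the same |kappa|
  R <- rot3(0.4, -1.1, 2.2)
  kr <- signed_curvature(list(hx %*% t(R)), s_hx)
  expect_equal(abs(kr[1, mid]), abs(kh[1, mid]), tolerance = 1e-9)
})

test_that("Welch spectra localize beat frequencies", {
  fs <- 500
  t <- (0:1499) / fs
  x <- sin(2 * pi * 25 * t)
  ps <- power_spectrum(x, fs)
  expect_equal(ps$peak_freq, 25)        # grid resolution 2.5 Hz
  expect_false(ps$short_series)
  # half-amplitude second component: PSD ratio ~ 1/4
  x2 <- sin(2 * pi * 25 * t) + 0.5 * sin(2 * pi * 50 * t)
  ps2 <- power_spectrum(x2, fs)
  i25 <- which.min(abs(ps2$freq - 25)); i50 <- which.min(abs(ps2$freq - 50))
  expect_lt(abs(ps2$psd[i50] / ps2$psd[i25] - 0.25), 0.025)
  # white noise: no peak above 5x the median (detection floor)
  noise <- mfitrack:::with_seed(77, function() rnorm(1500))
  psn <- power_spectrum(noise, fs)
  expect_lt(max(psn$psd[-1]), 5 * median(psn$psd[-1]) * 3)
  # short series falls back to a flagged single periodogram
  pss <- power_spectrum(x[1:100], fs)
  expect_true(pss$short_series)
})

test_that("harmonic components follow the amplitude convention", {
  fs <- 500
  t <- (0:(2 * fs - 1)) / fs            # 2 s
  x <- 0.02 + 0.05 * cos(2 * pi * 25 * t) + 0.006 * cos(4 * pi * 25 * t)
  hc <- harmonic_components(x, fs, f0 = 25)
  expect_lt(abs(hc$c0 / 0.020 - 1), 0.02)
  expect_lt(abs(hc$c1 / 0.050 - 1), 0.02)
  expect_lt(abs(hc$c2 / 0.006 - 1), 0.02)
  # constant signal -> (|k|, 0, 0)
  hcc <- harmonic_components(rep(-0.03, 1000), fs, f0 = 25)
  expect_equal(hcc$c0, 0.03)
  expect_lt(hcc$c1, 1e-12); expect_lt(hcc$c2, 1e-12)
  # linearity: doubling the signal doubles all three amplitudes
  h2 <- harmonic_components(2 * x, fs, f0 = 25)
  expect_equal(h2$c0 / hc$c0, 2, tolerance = 1e-9)
  expect_equal(h2$c1 / hc$c1, 2, tolerance = 1e-9)
  expect_equal(h2$c2 / hc$c2, 2, tolerance = 1e-9)
  # f0 can be estimated from the spectrum
  hce <- harmonic_components(x, fs)
  expect_equal(hce$f0, 25)
  expect_error(harmonic_components(x[1:30], fs, f0 = 25), "cycles")
})

test_that("swim speed from rlowess-smoothed trajectories", {
  fs <- 500
  n <- 400
  t <- (0:(n - 1)) / fs
  # straight-line motion at 50 um/s with 0.1-um jitter
  jitter <- mfitrack:::with_seed(5, function() {
    matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
  })
  pos <- cbind(50 * t, 0, 0) + jitter
  sp <- swim_speed(pos, fs)
  expect_lt(abs(sp$mean_speed / 50 - 1), 0.04)
  # stationary -> ~0
  pos0 <- matrix(1, n, 3)
  expect_lt(swim_speed(pos0, fs)$mean_speed, 1e-9)
  # circular path radius 25 um at 2 rad/s -> speed 50 um/s within 5%
  th <- 2 * t
  circ <- cbind(25 * cos(th), 25 * sin(th), 0)
  spc <- swim_speed(circ, fs)
  expect_lt(abs(spc$mean_speed / 50 - 1), 0.05)
})
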