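test_that("weighted circle fit is exact on circles and matches the oracle", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  x <- 10 + 5 * cos(th); y <- 10 + 5 * sin(th)
  f <- fit_circle_weighted(data.frame(x = x, y = y, I = 1))
  expect_equal(c(f$xc, f$yc, f$radius), c(10, 10, 5), tolerance = 1e-10)
  # exact data: heterogeneous weights give the identical result
  f2 <- fit_circle_weighted(data.frame(x = x, y = y, I = runif(8, 1, 50)))
  expect_equal(c(f2$xc, f2$yc, f2$radius), c(10, 10, 5), tolerance = 1e-8)
  # 100 random noisy intensity-weighted patches vs brute-force WLS
  set.seed(42)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    cx <- runif(1, -5, 5); cy <- runif(1, -5, 5); r <- runif(1, 2, 8)
    a <- runif(n, 0, 2 * pi)
    px <- cx + r * cos(a) + rnorm(n, sd = 0.1)
    py <- cy + r * sin(a) + rnorm(n, sd = 0.1)
    I <- runif(n, 0.5, 10)
    got <- fit_circle_weighted(data.frame(x = px, y = py, I = I))
    want <- oracle_circle_wls(px, py, I)
    expect_equal(got$xc, as.numeric(want$xc), tolerance = 1e-9)
    expect_equal(got$yc, as.numeric(want$yc), tolerance = 1e-9)
    expect_equal(got$radius, as.numeric(want$radius), tolerance = 1e-9)
  }
  # collinear pixels -> singular fit
  expect_error(
    fit_circle_weighted(data.frame(x = 1:6, y = 2 * (1:6) + 1, I = 1)),
    "singular|degenerate")
})

test_that("LoG bead detection finds beads with subpixel accuracy", {
  cfg <- std_config()
  psf <- std_psf()
  blank <- matrix(0, 80, 80)
  expect_equal(nrow(detect_beads(blank, 10, 10)), 0)
  sc <- scene_spec(list(scene_bead(c(13.75, 13.75, 2))), seed = 5)
  fr <- render_multifocal_frame(sc, cfg, psf)
  proj <- preprocess_video(list(fr))$projection[[1]]
  det <- detect_beads(proj, diameter_px = 10, threshold = 10)
  expect_equal(nrow(det), 1)
  truth <- 13.75 / cfg$pixel_pitch
  expect_lt(sqrt((det$x - truth)^2 + (det$y - truth)^2), 0.3)
  # two beads three diameters apart -> two detections
  sc2 <- scene_spec(list(scene_bead(c(9, 13.75, 2)),
                         scene_bead(c(19.3, 13.75, 2))), seed = 6)
  fr2 <- render_multifocal_frame(sc2, cfg, psf)
  det2 <- detect_beads(preprocess_video(list(fr2))$projection[[1]], 10, 10)
  expect_equal(nrow(det2), 2)
})

test_that("preprocessing removes static structures, keeps moving beads", {
  cfg <- std_config()
  psf <- std_psf()
  frames <- lapply(1:6, function(i) {
    sc <- scene_spec(list(
      scene_bead(c(8, 8, 2)),                       # static
      scene_bead(c(10 + i * 1.5, 18, 2))),          # moving
      seed = 100 + i)
    render_multifocal_frame(sc, cfg, psf)
  })
  pp <- preprocess_video(frames, subtract_static = TRUE)
  mid <- pp$projection[[3]]
  px <- function(um) round(um / cfg$pixel_pitch) + 1
  expect_lt(mid[px(8), px(8)], 5)                      # static bead removed
  expect_gt(mid[px(18), px(10 + 3 * 1.5)], 10)         # moving bead kept
  # static scene with subtraction -> projection ~ 0 everywhere
  statics <- lapply(1:4, function(i) {
    render_multifocal_frame(
      scene_spec(list(scene_bead(c(8, 8, 2))), noise_sd_frac = 0), cfg, psf)
  })
  pp0 <- preprocess_video(statics, subtract_static = TRUE)
  expect_lt(max(pp0$projection[[2]]), 1e-9)
  expect_error(preprocess_video(statics[1], subtract_static = TRUE),
               "at least 2")
})

test_that("radius calibration aligns, averages and propagates precision", {
  fx <- bead_fixture_small()
  # two identical profiles offset by exactly +1.0 um -> recovered offset
  zs <- fx$zs
  base <- measure_radius_profile(zs, fx$cfg, fx$psf, seed = 77,
                                 noise_sd_frac = 0)
  shifted <- apply(base, 2, function(col) {
    stats::approx(zs + 1.0, col, zs, rule = 2)$y
  })
  cal2 <- build_radius_calibration(list(base, shifted), zs)
  expect_lt(abs(abs(cal2$offsets[2]) - 1.0), 0.05)
  # single noiseless bead: curve equals its own (smoothed) profile, sigma_R=0
  cal1 <- build_radius_calibration(list(base), zs)
  expect_true(all(cal1$sigma_r == 0))
  sm <- apply(base, 2, mfitrack:::moving_average,
              w = 2L * floor(2 / 0.3 / 2) + 1L)
  expect_equal(cal1$r, sm, tolerance = 1e-9)
  # noisy multi-bead calibration: precision diverges at each plane's focus
  # relative to the steep flanks
  calib <- fx$calib
  for (k in 1:4) {
    focus <- fx$cfg$plane_offsets[k]
    sz_focus <- mfitrack:::sigma_z_at(calib, k, focus)
    sz_flank <- mfitrack:::sigma_z_at(calib, k, focus + 6)
    expect_gt(sz_focus, sz_flank)
  }
})

test_that("combined z-precision improves with more planes", {
  calib <- bead_fixture_small()$calib
  p1 <- predict_z_precision(calib, 1)
  expect_equal(p1$sigma_z, calib$sigma_z[, 1])
  prev <- p1
  for (k in 2:4) {
    cur <- predict_z_precision(calib, 1:k)
    expect_true(all(cur$sigma_z <= prev$sigma_z + 1e-12))
    prev <- cur
  }
  p_all <- predict_z_precision(calib)
  expect_lt(p_all$mean_sigma_z,
            min(vapply(1:4, function(k) {
              predict_z_precision(calib, k)$mean_sigma_z
            }, numeric(1))))
  expect_error(predict_z_precision(calib, integer(0)), "empty")
})

test_that("z-inference recovers depth and enforces exclusion rules", {
  fx <- bead_fixture_small()
  ctr_px <- (fx$cfg$fov_px[1] - 1) / 2
  # rendered bead at z = +3: inferred within 2 sigma_z
  stack <- render_bead_zstack(3.0, fx$cfg, fx$psf, seed = 321)
  rr <- measure_bead_radii(stack[[1]], ctr_px, ctr_px)
  res <- infer_bead_z(rr, fx$calib)
  expect_false(res$excluded)
  expect_lt(abs(res$z - 3.0), 2 * max(res$sigma_z, 0.3))
  # r2 > 0.8 in only one plane -> excluded with the stated reason
  rr_bad <- rr
  rr_bad$r2 <- c(0.95, 0.5, 0.5, 0.5)
  res_bad <- infer_bead_z(rr_bad, fx$calib)
  expect_true(res_bad$excluded)
  expect_match(res_bad$reason, "insufficient valid planes")
  expect_true(is.na(res_bad$z))
  # single-plane case is ambiguous: both candidates reported
  expect_true(res_bad$ambiguous)
  expect_length(res_bad$candidates, 1)
  expect_equal(length(res_bad$candidates[[1]]), 2)
})

test_that("track linking respects the 1.5-um rule and keeps identities", {
  # one bead drifting 0.1 um/frame -> a single full-length track
  drift <- data.frame(frame = 1:30, x = 0.1 * (1:30), y = 0, z = 0)
  lk <- link_tracks(drift)
  expect_equal(length(unique(lk$track)), 1)
  # a 1.6-um jump breaks the track
  jump <- data.frame(frame = 1:10, x = c(rep(0, 5), rep(1.6, 5)) + 0.01 * (1:10),
                     y = 0, z = 0)
  lk2 <- link_tracks(jump)
  expect_equal(length(unique(lk2$track)), 2)
  expect_equal(length(unique(lk2$track[1:5])), 1)
  # two beads approaching to 5 um never swap ids
  set.seed(9)
  n <- 40
  a <- data.frame(frame = 1:n, x = seq(0, 10, length.out = n), y = 0, z = 0,
                  truth = 1)
  b <- data.frame(frame = 1:n, x = seq(15, 10.2, length.out = n) + 5,
                  y = 5, z = 0, truth = 2)
  both <- rbind(a, b)
  both$x <- both$x + rnorm(2 * n, sd = 0.05)
  lk3 <- link_tracks(both)
  tab <- table(lk3$track, lk3$truth)
  expect_true(all(apply(tab > 0, 1, sum) == 1))  # each track pure in truth
})
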