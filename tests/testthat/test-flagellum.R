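test_that("sharpest-plane selection uses intensity standard deviation", {
  cfg <- std_config()
  psf <- std_psf()
  pts <- cbind(seq(5, 22, length.out = 60), 13.75, cfg$plane_offsets[2])
  fr <- render_multifocal_frame(
    scene_spec(list(scene_filament(pts)), noise_sd_frac = 0), cfg, psf)
  expect_equal(select_sharpest_plane(fr), 2L)
  # identical planes -> plane 1 by the tie rule
  same <- multifocal_frame(rep(fr$planes[3], 4), fr$plane_offsets)
  expect_equal(select_sharpest_plane(same), 1L)
  # adding a uniform offset to one plane does not change the outcome
  fr$planes[[4]] <- fr$planes[[4]] + 500
  expect_equal(select_sharpest_plane(fr), 2L)
})

test_that("centerline extraction recovers straight and curved filaments", {
  cfg <- optics_config(fov_px = c(176L, 176L))
  psf <- std_psf()
  pitch <- cfg$pixel_pitch
  # straight filament of length 40 um, in focus in plane 1
  pts <- cbind(seq(10, 50, length.out = 200), 30, 0)
  fr <- render_multifocal_frame(
    scene_spec(list(scene_filament(pts)), noise_sd_frac = 0), cfg, psf)
  tr <- extract_centerline_2d(fr$planes[[1]], pixel_pitch = pitch,
                              head_anchor = FALSE)
  expect_lt(abs(max(tr$points$s) - 40), 0.5)
  expect_lt(max(abs(tr$points$y * pitch - 30)), 0.3 * pitch)
  # arc of curvature 0.05: recovered pointwise curvature 0.05 +- 0.005
  arc <- simulate_flagellar_beat(
    beat_waveform_spec(c0 = 0.05, c1 = 0, c2 = 0, length_um = 40,
                       out_of_plane_amplitude = 0), 1, head_xy = c(10, 15))
  fra <- render_multifocal_frame(
    scene_spec(list(scene_filament(arc$frames[[1]])), noise_sd_frac = 0),
    cfg, psf)
  tra <- extract_centerline_2d(fra$planes[[1]], pixel_pitch = pitch,
                               head_anchor = FALSE)
  pxy <- cbind(tra$points$x, tra$points$y, 0) * pitch
  kap <- signed_curvature(list(pxy), tra$points$s)
  mid <- tra$points$s > 8 & tra$points$s < 32
  expect_lt(max(abs(abs(kap[1, mid]) - 0.05), na.rm = TRUE), 0.005)
  # blank image -> no-flagellum error
  expect_error(extract_centerline_2d(matrix(0, 64, 64) +
                                       matrix(rnorm(64 * 64, sd = 1e-3), 64),
                                     pixel_pitch = pitch),
               "no flagellum")
})

test_that("width profiles follow the defocus forward model", {
  cfg <- optics_config(fov_px = c(176L, 176L))
  psf <- std_psf()
  pitch <- cfg$pixel_pitch
  z_f <- 0   # plane 1 in focus
  pts <- cbind(seq(10, 50, length.out = 200), 30, z_f)
  fr <- render_multifocal_frame(
    scene_spec(list(scene_filament(pts)), noise_sd_frac = 0), cfg, psf)
  tr <- extract_centerline_2d(fr$planes[[select_sharpest_plane(fr)]],
                              pixel_pitch = pitch)
  wm <- measure_width_profile(fr, tr)
  mid <- wm[[1]]$s > 5 & wm[[1]]$s < 35
  # fitted width matches sqrt((w(dz)/sqrt 2)^2 + t^2/12) within 5%
  for (k in 1:4) {
    sig_pred <- sqrt(psf_width(z_f - cfg$plane_offsets[k], psf)^2 / 2 +
                       0.4^2 / 12)
    med <- median(wm[[k]]$width_um[mid], na.rm = TRUE)
    expect_lt(abs(med / sig_pred - 1), 0.05)
  }
  # every defocused plane is wider than the in-focus plane
  w_focus <- median(wm[[1]]$width_um[mid], na.rm = TRUE)
  for (k in 2:4) {
    expect_gt(median(wm[[k]]$width_um[mid], na.rm = TRUE), w_focus)
  }
  # sampling uniform background -> flagged (amplitude ~ 0)
  flat <- multifocal_frame(replicate(4, matrix(5, 176, 176),
                                     simplify = FALSE), fr$plane_offsets)
  wf <- measure_width_profile(flat, tr)
  expect_true(all(wf[[1]]$flagged))
})

test_that("width calibration maps are focused at dz = 0 and averaged", {
  fx <- flag_fixture()
  calib <- fx$calib
  # minimum width over dz lies near dz = 0 for every plane at mid arc length
  for (k in 1:4) {
    col <- calib$maps[[k]][, which.min(abs(calib$s - 25))]
    dz_min <- calib$dz[[k]][which.min(col)]
    expect_lt(abs(dz_min), 1.6)
  }
  # two identical noiseless cells average to either one
  cfg <- fx$cfg
  cell <- measure_width_stack(fx$base_pts, seq(-2, 10, by = 1.5), cfg,
                              fx$psf, noise_sd = 0, seed_base = 1)
  cal2 <- build_width_calibration(list(cell, cell), cfg$plane_offsets)
  cal1 <- build_width_calibration(list(cell), cfg$plane_offsets)
  expect_equal(cal2$maps, cal1$maps, tolerance = 1e-9)
})

test_that("width-based z-inference tracks the piezo (slope ~ 1)", {
  fx <- flag_fixture()
  piezo_test <- seq(-1, 7, by = 2)
  z_hat <- numeric(length(piezo_test))
  for (i in seq_along(piezo_test)) {
    pts <- fx$base_pts
    pts[, 3] <- pts[, 3] + piezo_test[i]
    fr <- render_flagellum_frame(pts, fx$cfg, fx$psf, fx$noise_sd,
                                 seed = 600 + i)
    tr3 <- trace_flagellum_3d(fr, fx$calib)
    sel <- tr3$s > 10 & tr3$s < 45
    z_hat[i] <- mean(tr3$z[sel], na.rm = TRUE)
    # per-point residual scatter stays bounded
    expect_lt(sd(tr3$z[sel] - piezo_test[i], na.rm = TRUE), 1.2)
  }
  fit <- lm(z_hat ~ piezo_test)
  expect_lt(abs(coef(fit)[2] - 1), 0.08)
  # width exactly at the in-focus minimum -> single candidate at dz ~ 0
  calib <- fx$calib
  js <- which.min(abs(calib$s - 25))
  col <- calib$maps[[1]][, js]
  cv <- mfitrack:::invert_width_column(calib$dz[[1]], col, min(col))
  expect_length(as.numeric(cv), 1)
  expect_lt(abs(as.numeric(cv) - calib$dz[[1]][which.min(col)]), 1e-9)
})

test_that("intensity-based z-inference fits the plane profile", {
  offsets <- seq(0, 8.8, length.out = 4)
  mk_widths <- function(peaks) {
    lapply(seq_along(peaks), function(k) {
      data.frame(s = c(0, 1), width_um = 1, peak = peaks[k],
                 center_offset_px = 0, flagged = FALSE)
    })
  }
  # intensities symmetric about plane 2's offset -> z = that offset
  g <- function(z0) exp(-(offsets - z0)^2 / 8)
  r1 <- infer_z_from_intensity(mk_widths(g(offsets[2])), offsets)
  expect_equal(r1$z[1], offsets[2], tolerance = 1e-6)
  expect_false(r1$flagged[1])
  # source between planes 2 and 3 -> recovered within 0.5 um
  z0 <- (offsets[2] + offsets[3]) / 2 + 0.4
  r2 <- infer_z_from_intensity(mk_widths(g(z0)), offsets)
  expect_lt(abs(r2$z[1] - z0), 0.5)
  # monotone profile (object beyond the span) -> flagged unreliable
  r3 <- infer_z_from_intensity(mk_widths(g(15)), offsets)
  expect_true(r3$flagged[1])
})

test_that("arc-length smoothing preserves structure, kills outliers", {
  z <- rep(2, 101)
  expect_equal(smooth_arclength(z), z)
  # +3-um single-point spike suppressed below 0.5 um
  spike <- z; spike[51] <- 5
  sm <- smooth_arclength(spike)
  expect_lt(max(abs(sm - 2)), 0.5)
  # linear ramp preserved within 1% away from the endpoints
  s <- seq(0, 50, by = 11 / 32)
  ramp <- 0.1 * s
  smr <- smooth_arclength(ramp)
  inner <- seq_along(s) > 8 & seq_along(s) < length(s) - 8
  expect_lt(max(abs(smr[inner] - ramp[inner]) / pmax(ramp[inner], 0.5)), 0.01)
})
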