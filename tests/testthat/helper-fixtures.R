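# Shared synthetic fixtures, built once per test session (memoized in an
# environment). All fixtures are generated in code at test time; the only
# tunables are the stated-world parameters of the forward model.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

std_config <- function(fov = 80L) optics_config(fov_px = fov)
std_psf <- function() gaussian_psf()

# Per-bead, per-plane radius profile across a piezo sweep.
measure_radius_profile <- function(piezo_z, config, psf, seed,
                                   noise_sd_frac = 0.02) {
  ctr <- (config$fov_px - 1) / 2 * config$pixel_pitch
  stack <- render_bead_zstack(piezo_z, config, psf, seed = seed,
                              noise_sd_frac = noise_sd_frac)
  ctr_px <- (config$fov_px[1] - 1) / 2
  t(vapply(stack, function(fr) {
    measure_bead_radii(fr, ctr_px, ctr_px)$radius
  }, numeric(length(config$plane_offsets))))
}

# Small-scale bead calibration (coarse z grid) for unit/property tests.
bead_fixture_small <- function() fixture("bead_small", function() {
  cfg <- std_config()
  psf <- std_psf()
  zs <- seq(-10.5, 10.5, by = 0.3)
  profiles <- lapply(1:4, function(i) {
    measure_radius_profile(zs, cfg, psf, seed = 1000 + i * 100)
  })
  calib <- build_radius_calibration(profiles, zs)
  list(cfg = cfg, psf = psf, zs = zs, calib = calib)
})

# Immotile-cell width-measurement z-stack for the flagellum tests.
measure_width_stack <- function(base_pts, piezo, cfg, psf, noise_sd,
                                seed_base, head_brightness = 20000) {
  s_grid <- NULL
  wl <- vector("list", length(piezo))
  for (i in seq_along(piezo)) {
    pts <- base_pts
    pts[, 3] <- pts[, 3] + piezo[i]
    sc <- scene_spec(list(
      scene_filament(pts),
      scene_bead(c(pts[1, 1], pts[1, 2], pts[1, 3]), radius = 0.5,
                 brightness = head_brightness)),
      noise_sd = noise_sd, seed = seed_base + i)
    fr <- render_multifocal_frame(sc, cfg, psf)
    tr <- extract_centerline_2d(fr$planes[[select_sharpest_plane(fr)]],
                                pixel_pitch = cfg$pixel_pitch)
    wl[[i]] <- measure_width_profile(fr, tr)
    if (is.null(s_grid)) s_grid <- wl[[i]][[1]]$s
  }
  n_pl <- length(cfg$plane_offsets)
  arr <- array(NA_real_, c(length(piezo), length(s_grid), n_pl))
  for (i in seq_along(piezo)) for (k in seq_len(n_pl)) {
    wi <- wl[[i]][[k]]
    arr[i, , k] <- stats::approx(wi$s, ifelse(wi$flagged, NA, wi$width_um),
                                 s_grid, rule = 1)$y
  }
  list(s = s_grid, piezo_z = piezo, width = arr)
}

flag_fixture <- function() fixture("flag", function() {
  cfg <- optics_config(fov_px = c(176L, 176L))
  psf <- std_psf()
  static <- simulate_flagellar_beat(
    beat_waveform_spec(c0 = 0.02, c1 = 0, c2 = 0, out_of_plane_amplitude = 0),
    1, head_xy = c(8, 20))
  base_pts <- static$frames[[1]]
  sc0 <- scene_spec(list(scene_filament(base_pts)), noise_sd_frac = 0)
  fil_peak <- max(render_multifocal_frame(sc0, cfg, psf)$planes[[1]])
  noise_sd <- 0.02 * fil_peak
  piezo <- seq(-5, 13, by = 0.75)
  cells <- lapply(1:4, function(ci) {
    measure_width_stack(base_pts, piezo, cfg, psf, noise_sd, 4000 * ci)
  })
  calib <- build_width_calibration(cells, cfg$plane_offsets)
  list(cfg = cfg, psf = psf, base_pts = base_pts, piezo = piezo,
       noise_sd = noise_sd, cells = cells, calib = calib,
       fil_peak = fil_peak)
})

# End-to-end beat reconstruction at the acceptance scale: 10 calibration
# cells (full protocol: 12) at 0.6-um piezo steps (full protocol: 0.1 um)
# and 216 frames at 500 fps. Shared between the acceptance criterion and
# the full-chain property test.
beat_e2e_fixture <- function() fixture("beat_e2e", function() {
  fx <- flag_fixture()
  cfg <- fx$cfg; psf <- fx$psf
  piezo <- seq(-5, 13, by = 0.6)
  cells <- lapply(1:10, function(ci) {
    measure_width_stack(fx$base_pts, piezo, cfg, psf, fx$noise_sd,
                        40000 * ci)
  })
  calib <- build_width_calibration(cells, cfg$plane_offsets)
  spec <- beat_waveform_spec()    # 25 Hz, C = (0.02, 0.05, 0.006), 500 fps
  n_frames <- 216
  beat <- simulate_flagellar_beat(spec, n_frames, head_xy = c(8, 30),
                                  z0 = 4.4)
  frames <- lapply(seq_len(n_frames), function(fi) {
    render_flagellum_frame(beat$frames[[fi]], cfg, psf, fx$noise_sd,
                           seed = 30000 + fi, timestamp = beat$t[fi])
  })
  rec <- reconstruct_beat(frames, calib)
  list(cfg = cfg, psf = psf, calib = calib, beat = beat, rec = rec,
       n_frames = n_frames)
})

render_flagellum_frame <- function(pts, cfg, psf, noise_sd, seed,
                                   timestamp = 0, head_brightness = 20000) {
  sc <- scene_spec(list(
    scene_filament(pts),
    scene_bead(c(pts[1, 1], pts[1, 2], pts[1, 3]), radius = 0.5,
               brightness = head_brightness)),
    noise_sd = noise_sd, seed = seed)
  render_multifocal_frame(sc, cfg, psf, timestamp = timestamp)
}
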