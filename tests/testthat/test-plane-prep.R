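identity_transform_test <- function() list(scale = 1, theta = 0, tx = 0, ty = 0)

local_var_test <- function(img, cx, cy, h = 4) {
  patch <- img[(cy - h):(cy + h), (cx - h):(cx + h)]
  var(as.numeric(patch))
}

make_blank <- function(maps, level = 100) {
  multifocal_frame(lapply(maps, function(m) level * m),
                   plane_offsets = seq(0, 8.8, length.out = length(maps)))
}

test_that("intensity normalization flattens the blank and is linear", {
  ny <- 64; nx <- 64
  # uniform blank -> map of ones, normalization is the identity
  flat <- make_blank(replicate(4, matrix(1, ny, nx), simplify = FALSE))
  m1 <- build_intensity_map(flat)
  expect_true(all(abs(unlist(m1) - 1) < 1e-9))
  # plane 2 attenuated by 0.5: identical scenes equalize after normalization
  att <- make_blank(list(matrix(1, ny, nx), matrix(0.5, ny, nx),
                         matrix(1, ny, nx), matrix(1, ny, nx)))
  m2 <- build_intensity_map(att)
  scene <- matrix(runif(ny * nx, 50, 150), ny)
  fr <- multifocal_frame(list(scene, 0.5 * scene, scene, scene),
                         seq(0, 8.8, length.out = 4))
  nf <- normalize_planes(fr, m2)
  expect_lt(abs(mean(nf$planes[[2]]) / mean(nf$planes[[1]]) - 1), 0.01)
  # synthetic radial vignette (20% falloff): normalized blank flat within 1%
  xg <- matrix(rep(seq(-1, 1, length.out = nx), each = ny), ny)
  yg <- matrix(rep(seq(-1, 1, length.out = ny), nx), ny)
  vig <- 1 - 0.2 * (xg^2 + yg^2) / 2
  blank <- make_blank(replicate(4, vig, simplify = FALSE))
  mv <- build_intensity_map(blank)
  nb <- normalize_planes(blank, mv)
  for (p in nb$planes) expect_lt(sd(p) / mean(p), 0.01)
  # linearity: normalize(a * I) = a * normalize(I)
  n1 <- normalize_planes(fr, m2)
  fr3 <- fr; fr3$planes <- lapply(fr$planes, function(p) 3 * p)
  n3 <- normalize_planes(fr3, m2)
  expect_equal(n3$planes[[1]], 3 * n1$planes[[1]], tolerance = 1e-12)
  # invalid map rejected
  bad <- m2; bad[[1]][1, 1] <- 0
  expect_error(normalize_planes(fr, bad), "invalid")
})

grid_frame <- function(cfg = optics_config(fov_px = 128),
                       psf = std_psf(), z = 2) {
  render_multifocal_frame(
    scene_spec(list(scene_grid(pitch = 8, z = z)), noise_sd_frac = 0),
    cfg, psf)
}

test_that("grid registration recovers injected transforms", {
  gf <- grid_frame()
  # identical planes -> identity transforms, near-zero residual
  same <- multifocal_frame(rep(gf$planes[1], 4), gf$plane_offsets)
  m0 <- register_planes_from_grid(same)
  for (tr in m0$transforms) {
    expect_lt(abs(tr$tx), 0.05); expect_lt(abs(tr$ty), 0.05)
    expect_lt(abs(tr$scale - 1), 5e-4)
  }
  # inject a (+4, -2.5) px shift on plane 3 and a 1.01 scale about the
  # image center on plane 4
  ctr <- (128 - 1) / 2
  inj <- registration_model(list(
    identity_transform_test(), identity_transform_test(),
    list(scale = 1, theta = 0, tx = 4, ty = -2.5),
    list(scale = 1.01, theta = 0, tx = ctr * (1 - 1.01),
         ty = ctr * (1 - 1.01))))
  shifted <- apply_registration(gf, inj)
  m <- register_planes_from_grid(shifted)
  # recovered transform maps the shifted plane back onto plane 1
  expect_lt(abs(m$transforms[[3]]$tx - (-4)), 0.2)
  expect_lt(abs(m$transforms[[3]]$ty - 2.5), 0.2)
  expect_lt(abs(m$transforms[[4]]$scale - 1 / 1.01), 0.002)
  # registration residual decreases from pre- to post-alignment
  aligned <- apply_registration(shifted, m)
  pre <- mean(abs(shifted$planes[[3]] - shifted$planes[[1]]))
  post <- mean(abs(aligned$planes[[3]] - aligned$planes[[1]]))
  expect_lt(post, pre)
})

test_that("apply_registration identity and inverse behave", {
  gf <- grid_frame()
  idm <- registration_model(replicate(4, identity_transform_test(),
                                      simplify = FALSE))
  expect_identical(apply_registration(gf, idm)$planes, gf$planes)
  # apply then apply the inverse: back to the original within interpolation
  fwd <- registration_model(list(
    identity_transform_test(), list(scale = 1, theta = 0, tx = 3, ty = -2),
    identity_transform_test(), identity_transform_test()))
  inv <- registration_model(list(
    identity_transform_test(), list(scale = 1, theta = 0, tx = -3, ty = 2),
    identity_transform_test(), identity_transform_test()))
  rt <- apply_registration(apply_registration(gf, fwd), inv)
  rng <- diff(range(gf$planes[[2]]))
  interior <- 10:118
  expect_lt(max(abs(rt$planes[[2]][interior, interior] -
                      gf$planes[[2]][interior, interior])), 0.01 * rng)
})

test_that("interplane distances come from the sharpness maxima", {
  cfg <- optics_config(fov_px = 96, plane_offsets = c(0, 3, 6, 9))
  psf <- std_psf()
  piezo <- seq(-2, 11, by = 0.25)
  stack <- lapply(piezo, function(z) grid_frame(cfg, psf, z = z))
  offs <- estimate_interplane_distances(stack, piezo)
  expect_equal(as.numeric(offs), c(0, 3, 6, 9), tolerance = 0.05)
  # order invariance
  offs_rev <- estimate_interplane_distances(rev(stack), rev(piezo))
  expect_equal(as.numeric(offs_rev), as.numeric(offs), tolerance = 1e-9)
  # uniform intensity scaling leaves the estimate unchanged
  stack2 <- lapply(stack, function(fr) {
    fr$planes <- lapply(fr$planes, function(p) 3.7 * p)
    fr
  })
  offs_scaled <- estimate_interplane_distances(stack2, piezo)
  expect_equal(as.numeric(offs_scaled), as.numeric(offs), tolerance = 1e-9)
  # single-plane stack -> offset vector {0}
  one <- lapply(stack, function(fr) {
    multifocal_frame(fr$planes[1], fr$plane_offsets[1])
  })
  expect_equal(as.numeric(estimate_interplane_distances(one, piezo)), 0)
  # unbracketed focus -> warning + boundary flag
  short <- stack[piezo < 5]
  w <- capture_warnings(
    ob <- estimate_interplane_distances(short, piezo[piezo < 5]))
  expect_match(w, "boundary", all = FALSE)
  expect_true(any(attr(ob, "boundary")))
})

test_that("EDOF depth map picks the sharpest plane per pixel", {
  cfg <- std_config()
  psf <- std_psf()
  # one bead in focus in plane 1, another in plane 3
  sc <- scene_spec(list(scene_bead(c(8, 13.75, cfg$plane_offsets[1])),
                        scene_bead(c(19, 13.75, cfg$plane_offsets[3]))),
                   noise_sd_frac = 0)
  fr <- render_multifocal_frame(sc, cfg, psf)
  res <- edof_depth_map(fr, window_px = 9)
  px <- function(um) round(um / cfg$pixel_pitch) + 1
  expect_equal(res$depth[px(13.75), px(8)], 1L)
  expect_equal(res$depth[px(13.75), px(19)], 3L)
  # EDOF shows each bead at its sharpest-plane value
  expect_equal(res$edof[px(13.75), px(8)], fr$planes[[1]][px(13.75), px(8)])
  # identical planes -> tie-break to the lowest index
  same <- multifocal_frame(rep(fr$planes[2], 4), fr$plane_offsets)
  expect_true(all(edof_depth_map(same, 9)$depth == 1L))
  # EDOF local variance at an object >= any single plane's
  v_edof <- local_var_test(res$edof, px(8), px(13.75))
  for (k in 2:4) {
    expect_gte(v_edof, local_var_test(fr$planes[[k]], px(8), px(13.75)))
  }
})

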