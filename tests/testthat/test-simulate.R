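test_that("noise-free render: summed peak equals offset + true peak", {
  cond <- condition_spec(theta_sd_deg = 0, brightness_cv = 0)
  roi <- roi_ellipse(32, 32, 20, 20)
  sc <- scene_spec(image_shape_px = c(65, 65), nuclear_roi = roi,
                   n_npcs = 1, background_photon_level = 0,
                   condition = cond, seed = 3)
  ds <- render_sequence(sc, noise = FALSE)
  pair <- sum_frames(ds$stack)
  m <- pair$frames_summed_per_pol
  cam <- camera_model()
  # spot center is sub-pixel; compare at the pixel-sampled peak value
  x0 <- ds$truth$x_px; y0 <- ds$truth$y_px
  px <- round(x0); py <- round(y0)
  atten <- exp(-((px - x0)^2 + (py - y0)^2) / (2 * sc$psf_sigma_px^2))
  expect_equal(max(pair$p_image),
               cam$offset_counts * m + ds$truth$true_p_peak * atten,
               tolerance = 1e-10)
  expect_equal(max(pair$s_image),
               cam$offset_counts * m + ds$truth$true_s_peak * atten,
               tolerance = 1e-10)
  expect_equal(ds$truth$true_ps_ratio,
               ds$truth$true_p_peak / ds$truth$true_s_peak)
})

test_that("rendering is deterministic given the scene seed", {
  sc <- small_scene(seed = 11)
  a <- render_sequence(sc)
  b <- render_sequence(sc)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  d <- render_sequence(small_scene(seed = 12))
  expect_false(identical(a$stack$frames, d$stack$frames))
})

test_that("stacks alternate polarizations and round-trip through disk", {
  sc <- small_scene(seed = 5, n_npcs = 6)
  ds <- render_sequence(sc)
  expect_identical(ds$stack$pol_sequence, rep(c("p", "s"), 10))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, sc)
  back <- read_dataset(dir)
  expect_identical(back$stack$pol_sequence, ds$stack$pol_sequence)
  expect_equal(back$stack$frames, lapply(ds$stack$frames, round))
  expect_equal(back$truth$true_ps_ratio, ds$truth$true_ps_ratio)
  expect_equal(back$meta$seed, 5)
  # identical scene writes byte-identical TIFFs
  dir2 <- withr::local_tempdir()
  write_dataset(render_sequence(sc), dir2, sc)
  expect_identical(readBin(file.path(dir, "stack.tif"), "raw", 1e7),
                   readBin(file.path(dir2, "stack.tif"), "raw", 1e7))
})

test_that("photon totals are conserved in noise-free frames", {
  cond <- condition_spec(theta_sd_deg = 0, brightness_cv = 0)
  sc <- scene_spec(image_shape_px = c(96, 96), n_npcs = 5,
                   background_photon_level = 0, condition = cond, seed = 9)
  ds <- render_sequence(sc, noise = FALSE)
  pair <- sum_frames(ds$stack)
  cam <- camera_model()
  spot_counts <- sum(pair$p_image) -
    cam$offset_counts * pair$frames_summed_per_pol * 96 * 96
  expected <- sum(ds$truth$true_p_peak) * 2 * pi * sc$psf_sigma_px^2
  expect_lt(abs(spot_counts / expected - 1), 1e-3)
})

test_that("p frames carry the p field and s frames the s field", {
  # an in-plane dipole with no wobble: frame peak ratio = ix_p / ix_s
  cond <- condition_spec(
    ensemble = dipole_ensemble(90, wobble_half_angle_deg = 0,
                               brightness = 500),
    theta_sd_deg = 0, brightness_cv = 0)
  roi <- roi_ellipse(32, 32, 20, 20)
  sc <- scene_spec(image_shape_px = c(65, 65), nuclear_roi = roi, n_npcs = 1,
                   background_photon_level = 0, condition = cond, seed = 2)
  ds <- render_sequence(sc, noise = FALSE)
  cam <- camera_model()
  f <- default_fields()
  peak_p <- max(ds$stack$frames[[1]]) - cam$offset_counts
  peak_s <- max(ds$stack$frames[[2]]) - cam$offset_counts
  expect_equal(peak_p / peak_s, f$p$ix / f$s$ix, tolerance = 1e-10)
})

test_that("noisy renders scatter around the noise-free peak", {
  # per seed, the position draws precede the noise draws, so the clean
  # render with the same seed is the exact reference for each replicate
  cond <- condition_spec(theta_sd_deg = 0, brightness_cv = 0)
  roi <- roi_ellipse(24, 24, 14, 14)
  make_scene <- function(s) {
    scene_spec(image_shape_px = c(49, 49), nuclear_roi = roi, n_npcs = 1,
               condition = cond, seed = s)
  }
  err <- vapply(1:200, function(s) {
    sc <- make_scene(s)
    clean <- sum_frames(render_sequence(sc, noise = FALSE)$stack)$p_image
    noisy <- sum_frames(render_sequence(sc, noise = TRUE)$stack)$p_image
    max(noisy) - max(clean)
  }, numeric(1))
  expect_lt(abs(mean(err)), 2 * stats::sd(err))
})

test_that("placement honors the ROI and the minimum separation", {
  sc <- scene_spec(image_shape_px = c(80, 80), n_npcs = 30,
                   min_separation_px = 6, seed = 21)
  ds <- render_sequence(sc)
  tr <- ds$truth
  expect_true(all(in_roi(sc$nuclear_roi, tr$x_px, tr$y_px)))
  d <- as.matrix(stats::dist(cbind(tr$x_px, tr$y_px)))
  diag(d) <- Inf
  expect_gte(min(d), 6)
  # an overcrowded ROI fails with an informative error
  expect_error(
    render_sequence(scene_spec(image_shape_px = c(32, 32), n_npcs = 50,
                               min_separation_px = 10, seed = 1)),
    "min_separation_px")
})

test_that("condition pairs record their manifest and clamp shifted angles", {
  base <- small_scene(seed = 31, n_npcs = 8)
  res <- generate_condition_pair(base, 20, seeds = c(31, 32))
  expect_identical(res$manifest$conditions, c("control", "perturbed"))
  expect_identical(res$manifest$seeds, c(31L, 32L))
  expect_false(res$manifest$clamped)
  expect_equal(mean(res$perturbed$truth$theta_d_deg) -
                 mean(res$control$truth$theta_d_deg), 20, tolerance = 2)
  # forward-predicted direction: larger polar angle, smaller p:s ratio
  expect_lt(median(res$perturbed$truth$true_ps_ratio),
            median(res$control$truth$true_ps_ratio))
  expect_warning(
    clamped <- generate_condition_pair(
      small_scene(seed = 33, n_npcs = 4,
                  condition = condition_spec(
                    ensemble = dipole_ensemble(170, wobble_half_angle_deg = 15,
                                               brightness = 350))),
      delta_theta_deg = 30, seeds = c(33, 34)),
    "clamped")
  expect_true(clamped$manifest$clamped)
  # null scenario: ground-truth ratio distributions agree up to noise
  null_pair <- generate_condition_pair(base, 0, seeds = c(41, 42))
  expect_gt(stats::t.test(null_pair$control$truth$true_ps_ratio,
                          null_pair$perturbed$truth$true_ps_ratio)$p.value,
            0.01)
})
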