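make_stack <- function(frames, labels = rep(c("p", "s"),
                                            length(frames) / 2)) {
  structure(list(frames = frames, pol_sequence = labels, exposure_ms = 5,
                 frame_interval_ms = 15),
            class = "frame_stack")
}

test_that("sum_frames sums per label without normalization", {
  unit <- matrix(1, 8, 8)
  stack <- make_stack(list(unit, unit, unit, unit))
  pair <- sum_frames(stack)
  expect_equal(pair$p_image, matrix(2, 8, 8))
  expect_equal(pair$s_image, matrix(2, 8, 8))
  expect_equal(pair$frames_summed_per_pol, 2)
  # a 20-frame alternating stack combines 10 frames per summed image
  big <- make_stack(replicate(20, unit, simplify = FALSE))
  expect_equal(sum_frames(big)$frames_summed_per_pol, 10)
  # summation commutes with frame order within a label
  f <- replicate(4, matrix(stats::runif(64), 8, 8), simplify = FALSE)
  a <- sum_frames(make_stack(f, c("p", "s", "p", "s")))
  b <- sum_frames(make_stack(f[c(3, 2, 1, 4)], c("p", "s", "p", "s")))
  expect_equal(a$p_image, b$p_image)
  expect_error(sum_frames(make_stack(list(unit, unit), c("p", "p"))),
               "per polarization")
  expect_error(sum_frames(make_stack(list(unit, unit), c("p", "q"))),
               "labels")
})

test_that("camera background subtraction scales with frames summed", {
  # per-frame constant 10, 10 frames per polarization: summed image is 100
  pair <- sum_frames(make_stack(replicate(20, matrix(10, 8, 8),
                                          simplify = FALSE)))
  out <- subtract_camera_background(pair, 10)
  expect_equal(out$p_image, matrix(0, 8, 8))
  # offset zero is the identity
  same <- subtract_camera_background(pair, 0)
  expect_equal(same$p_image, pair$p_image)
  # double subtraction is refused
  expect_error(subtract_camera_background(out, 10), "already")
  # values clip at zero
  low <- sum_frames(make_stack(replicate(2, matrix(1, 4, 4),
                                         simplify = FALSE)))
  expect_true(all(subtract_camera_background(low, 10)$p_image == 0))
})

test_that("background subtraction recovers the noise-free true peak", {
  cond <- condition_spec(theta_sd_deg = 0, brightness_cv = 0)
  roi <- roi_ellipse(32, 32, 20, 20)
  sc <- scene_spec(image_shape_px = c(65, 65), nuclear_roi = roi, n_npcs = 1,
                   background_photon_level = 0, condition = cond, seed = 8)
  ds <- render_sequence(sc, noise = FALSE)
  pair <- subtract_camera_background(sum_frames(ds$stack), 100)
  atten <- exp(-((round(ds$truth$x_px) - ds$truth$x_px)^2 +
                   (round(ds$truth$y_px) - ds$truth$y_px)^2) /
                 (2 * sc$psf_sigma_px^2))
  expect_equal(max(pair$p_image), ds$truth$true_p_peak * atten,
               tolerance = 1e-10)
})

test_that("LoG response equals the brute-force convolution oracle", {
  set.seed(14)
  img <- matrix(stats::runif(64 * 64, 0, 100), 64, 64)
  img <- add_gaussian_spot(img, 30.4, 22.7, 500, 1.3)
  for (sigma in c(1.0, 1.3, 2.0)) {
    fast <- log_response(img, sigma)
    slow <- direct_correlate(img, log_kernel(sigma))
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-6)
  }
})

test_that("detection finds isolated spots and nothing in blank images", {
  cfg <- analysis_config(roi = roi_ellipse(32, 32, 28, 28))
  blank <- structure(list(p_image = matrix(0, 64, 64),
                          s_image = matrix(0, 64, 64),
                          frames_summed_per_pol = 10, bg_subtracted = TRUE),
                     class = "timepoint_pair")
  expect_equal(nrow(detect_puncta(blank, cfg)), 0)
  # three well-separated noise-free spots localize within 1 px
  img <- matrix(0, 64, 64)
  centers <- cbind(x = c(20, 40, 28), y = c(20, 25, 45))
  for (i in 1:3) {
    img <- add_gaussian_spot(img, centers[i, 1], centers[i, 2], 400, 1.3)
  }
  pair <- structure(list(p_image = img, s_image = img,
                         frames_summed_per_pol = 10, bg_subtracted = TRUE),
                    class = "timepoint_pair")
  cand <- detect_puncta(pair, cfg)
  expect_equal(nrow(cand), 3)
  ord <- order(cand$x_px)
  for (k in 1:3) {
    i <- order(centers[, "x"])[k]
    expect_lt(max(abs(cand$x_px[ord[k]] - centers[i, "x"]),
                  abs(cand$y_px[ord[k]] - centers[i, "y"])), 1)
  }
  # unsubtracted input is refused
  pair$bg_subtracted <- FALSE
  expect_error(detect_puncta(pair, cfg), "background-subtracted")
})

test_that("edge candidates are flagged and excluded from fitting", {
  img <- matrix(0, 64, 64)
  img <- add_gaussian_spot(img, 2, 30, 400, 1.3)   # 2 px from the left edge
  img <- add_gaussian_spot(img, 30, 30, 400, 1.3)
  pair <- structure(list(p_image = img, s_image = img,
                         frames_summed_per_pol = 10, bg_subtracted = TRUE),
                    class = "timepoint_pair")
  cfg <- analysis_config(roi = NULL)
  cand <- detect_puncta(pair, cfg)
  expect_true(any(cand$edge))
  meas <- measure_ps(pair, fit_and_filter(pair, cand, cfg), cfg)
  edge_rows <- meas[meas$reject_reason == "edge", ]
  expect_true(all(!edge_rows$accepted))
  expect_true(all(is.na(edge_rows$ps_ratio)))
})

test_that("Gaussian fits recover noise-free spots and reject flat crops", {
  img <- matrix(5, 64, 64)
  img <- add_gaussian_spot(img, 30.3, 27.8, 400, 1.3)
  pair <- structure(list(p_image = img, s_image = img,
                         frames_summed_per_pol = 10, bg_subtracted = TRUE),
                    class = "timepoint_pair")
  cfg <- analysis_config(roi = NULL)
  cand <- detect_puncta(pair, cfg)
  meas <- fit_and_filter(pair, cand, cfg)
  expect_true(all(meas$accepted))
  expect_lt(abs(meas$p_x0 - 30.3), 0.1)
  expect_lt(abs(meas$p_y0 - 27.8), 0.1)
  expect_lt(abs(meas$p_sigma - 1.3), 0.1)
  # a candidate sitting on flat background fails acceptance
  flat_cand <- tibble::tibble(x_px = 10, y_px = 10, scale = 1.3,
                              response = 1, edge = FALSE)
  flat <- fit_and_filter(pair, flat_cand, cfg)
  expect_false(flat$accepted)
  expect_match(flat$reject_reason, "fit_failed")
})

test_that("a spot with no s signal is rejected as fit_failed_s", {
  # near-axial dipole, tiny wobble: p visible, s at noise level
  f <- default_fields()
  c2 <- poltirf:::mean_cos2_z(3, 2)
  img_p <- matrix(0, 64, 64)
  img_s <- matrix(0, 64, 64)
  amp <- 400
  img_p <- add_gaussian_spot(img_p, 30, 30, amp *
                               (f$p$ix * (1 - c2) + f$p$iz * c2), 1.3)
  img_s <- add_gaussian_spot(img_s, 30, 30, amp * f$s$ix * (1 - c2), 1.3)
  set.seed(4)
  img_p <- img_p + matrix(stats::rnorm(64 * 64, 0, 5), 64, 64)
  img_s <- img_s + matrix(stats::rnorm(64 * 64, 0, 5), 64, 64)
  pair <- structure(list(p_image = img_p, s_image = img_s,
                         frames_summed_per_pol = 10, bg_subtracted = TRUE),
                    class = "timepoint_pair")
  cfg <- analysis_config(roi = NULL)
  meas <- fit_and_filter(pair, detect_puncta(pair, cfg), cfg)
  expect_equal(nrow(meas), 1)
  expect_false(meas$accepted)
  expect_equal(meas$reject_reason, "fit_failed_s")
})

test_that("max-pixel ratios: arithmetic, symmetry and scaling equivariance", {
  img_p <- matrix(0, 48, 48); img_s <- matrix(0, 48, 48)
  img_p <- add_gaussian_spot(img_p, 24, 24, 200, 1.3)
  img_s <- add_gaussian_spot(img_s, 24, 24, 100, 1.3)
  pair <- structure(list(p_image = img_p, s_image = img_s,
                         frames_summed_per_pol = 10, bg_subtracted = TRUE),
                    class = "timepoint_pair")
  cfg <- analysis_config(roi = NULL)
  meas <- measure_ps(pair, fit_and_filter(pair, detect_puncta(pair, cfg),
                                          cfg), cfg)
  expect_equal(meas$ps_ratio, 2.0)
  # identical images give ratio 1 everywhere
  pair_same <- pair; pair_same$s_image <- pair$p_image
  m1 <- measure_ps(pair_same,
                   fit_and_filter(pair_same, detect_puncta(pair_same, cfg),
                                  cfg), cfg)
  expect_true(all(m1$ps_ratio[m1$accepted] == 1))
  # scaling both images by c scales maxima by c, leaves ratios unchanged
  pair_sc <- pair
  pair_sc$p_image <- 3.7 * pair$p_image
  pair_sc$s_image <- 3.7 * pair$s_image
  m2 <- measure_ps(pair_sc,
                   fit_and_filter(pair_sc, detect_puncta(pair_sc, cfg), cfg),
                   cfg)
  expect_equal(m2$ps_ratio, meas$ps_ratio)
  expect_equal(m2$p_max, 3.7 * meas$p_max)
  expect_equal(m2$s_max, 3.7 * meas$s_max)
})

test_that("integer translation shifts detections, not ratios", {
  set.seed(6)
  h <- 72
  img_p <- matrix(stats::rpois(h * h, 5), h, h)
  img_s <- matrix(stats::rpois(h * h, 5), h, h)
  img_p <- add_gaussian_spot(img_p, 30, 33, 300, 1.3)
  img_s <- add_gaussian_spot(img_s, 30, 33, 150, 1.3)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  cfg <- analysis_config(roi = NULL)
  as_pair <- function(p, s) {
    structure(list(p_image = p, s_image = s, frames_summed_per_pol = 10,
                   bg_subtracted = TRUE), class = "timepoint_pair")
  }
  m0 <- measure_ps(as_pair(img_p, img_s),
                   fit_and_filter(as_pair(img_p, img_s),
                                  detect_puncta(as_pair(img_p, img_s), cfg),
                                  cfg), cfg)
  p2 <- shift(img_p, 4, 7); s2 <- shift(img_s, 4, 7)
  m2 <- measure_ps(as_pair(p2, s2),
                   fit_and_filter(as_pair(p2, s2),
                                  detect_puncta(as_pair(p2, s2), cfg), cfg),
                   cfg)
  i0 <- which.max(m0$response); i2 <- which.max(m2$response)
  expect_equal(m2$x_px[i2] - m0$x_px[i0], 7)
  expect_equal(m2$y_px[i2] - m0$y_px[i0], 4)
  expect_equal(m2$ps_ratio[i2], m0$ps_ratio[i0])
})
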