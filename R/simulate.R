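# Synthetic pol-TIRF acquisition: renders alternating p/s frame stacks of
# diffraction-limited NPC puncta with Poisson shot noise, camera gain,
# Gaussian read noise and a constant camera offset, together with a
# ground-truth table, so every downstream stage is testable without real
# data.

#' Camera noise and digitization model
#'
#' @param offset_counts Constant additive camera background per frame
#'   (counts, >= 0).
#' @param counts_per_photon Gain (> 0).
#' @param read_noise_counts Gaussian read noise sd per frame (counts, >= 0).
#' @param bit_depth Digitizer bit depth; pixel values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(offset_counts = 100, counts_per_photon = 1,
                         read_noise_counts = 1.5, bit_depth = 16) {
  stopifnot(offset_counts >= 0, counts_per_photon > 0,
            read_noise_counts >= 0, bit_depth >= 8)
  structure(
    list(offset_counts = offset_counts,
         counts_per_photon = counts_per_photon,
         read_noise_counts = read_noise_counts,
         bit_depth = as.integer(bit_depth)),
    class = "camera_model")
}

#' Condition: the orientational state sampled per NPC
#'
#' Describes one experimental condition as a distribution of dipole
#' ensembles: a mean ensemble plus per-NPC Gaussian jitter of the polar
#' angle (complex-to-complex orientational heterogeneity) and log-normal
#' brightness variation (expression/incorporation variability).
#'
#' @param label Condition label.
#' @param ensemble Mean [dipole_ensemble()] for the condition.
#' @param theta_sd_deg Per-NPC sd of the dipole polar angle, degrees.
#' @param brightness_cv Per-NPC coefficient of variation of brightness.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(label = "control",
                           ensemble = dipole_ensemble(
                             polar_angle_deg = 45,
                             wobble_half_angle_deg = 15,
                             brightness = 350),
                           theta_sd_deg = 2, brightness_cv = 0.1) {
  stopifnot(inherits(ensemble, "dipole_ensemble"),
            theta_sd_deg >= 0, brightness_cv >= 0)
  structure(
    list(label = label, ensemble = ensemble, theta_sd_deg = theta_sd_deg,
         brightness_cv = brightness_cv),
    class = "condition_spec")
}

#' Synthetic scene specification
#'
#' Describes one field of view: image size, pixel size, the nuclear ROI
#' inside which NPCs are placed, how many NPCs, their minimum separation,
#' the PSF width, the out-of-spot background haze, the condition (per-NPC
#' orientation distribution), and the RNG seed. Defaults emulate the source
#' acquisition: 20 alternating p/s frames, a ~1.3 px Gaussian PSF at
#' 106 nm/px, and bright puncta (peak photon count chosen so the summed
#' p image has peak SNR near 20).
#'
#' @param image_shape_px `(height, width)` in pixels.
#' @param pixel_size_nm Pixel size, nm.
#' @param nuclear_roi [roi_ellipse()]/[roi_polygon()]; default an inscribed
#'   ellipse with an 8 px margin.
#' @param n_npcs Number of NPCs to place (>= 0).
#' @param min_separation_px Minimum center-to-center spot distance (> 0).
#' @param psf_sigma_px Gaussian PSF sd in pixels (> 0).
#' @param background_photon_level Mean out-of-spot photons per pixel per
#'   summed image.
#' @param condition A [condition_spec()].
#' @param seed Integer RNG seed; identical scenes render identically.
#' @param n_frames Total frame count, alternating p/s (even, default 20).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape_px = c(128, 128), pixel_size_nm = 106,
                       nuclear_roi = NULL, n_npcs = 50,
                       min_separation_px = 8, psf_sigma_px = 1.3,
                       background_photon_level = 10,
                       condition = condition_spec(), seed = 1,
                       n_frames = 20) {
  stopifnot(length(image_shape_px) == 2, all(image_shape_px >= 16),
            n_npcs >= 0, min_separation_px > 0, psf_sigma_px > 0,
            background_photon_level >= 0, n_frames >= 2,
            n_frames %% 2 == 0, inherits(condition, "condition_spec"))
  if (is.null(nuclear_roi)) nuclear_roi <- default_nuclear_roi(image_shape_px)
  stopifnot(inherits(nuclear_roi, "roi"))
  structure(
    list(image_shape_px = as.integer(image_shape_px),
         pixel_size_nm = pixel_size_nm, nuclear_roi = nuclear_roi,
         n_npcs = as.integer(n_npcs),
         min_separation_px = min_separation_px,
         psf_sigma_px = psf_sigma_px,
         background_photon_level = background_photon_level,
         condition = condition, seed = as.integer(seed),
         n_frames = as.integer(n_frames)),
    class = "scene_spec")
}

# Rejection-sample n positions uniformly inside the ROI honoring a minimum
# separation. 0-based sub-pixel coordinates.
sample_positions <- function(roi, n, min_sep, image_shape_px,
                             max_tries = 200 * max(n, 1)) {
  if (n == 0) return(tibble::tibble(x_px = numeric(0), y_px = numeric(0)))
  h <- image_shape_px[1]; w <- image_shape_px[2]
  xs <- numeric(0); ys <- numeric(0); tries <- 0
  while (length(xs) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop(sprintf(
        "could not place %d NPCs with min_separation_px = %g inside the ROI (placed %d)",
        n, min_sep, length(xs)), call. = FALSE)
    }
    x <- stats::runif(1, 0, w - 1)
    y <- stats::runif(1, 0, h - 1)
    if (!in_roi(roi, x, y)) next
    if (length(xs) > 0 && min((xs - x)^2 + (ys - y)^2) < min_sep^2) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  tibble::tibble(x_px = xs, y_px = ys)
}

# Add A * exp(-r^2 / (2 sigma^2)) sampled at pixel centers into `img`,
# restricted to a +/- 5 sigma window around the (0-based) center.
add_gaussian_spot <- function(img, x0, y0, amplitude, sigma) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(5 * sigma)
  r0 <- max(1, floor(y0 + 1) - half); r1 <- min(h, ceiling(y0 + 1) + half)
  c0 <- max(1, floor(x0 + 1) - half); c1 <- min(w, ceiling(x0 + 1) + half)
  rows <- r0:r1; cols <- c0:c1
  dy2 <- ((rows - 1) - y0)^2
  dx2 <- ((cols - 1) - x0)^2
  patch <- amplitude * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + patch
  img
}

#' Render a synthetic alternating-polarization frame stack
#'
#' Places NPCs in the nuclear ROI, samples each NPC's dipole polar angle and
#' brightness from the scene's condition, computes the expected p and s
#' excitation signals from the forward model, and renders `n_frames`
#' alternating p/s frames (p first). Per frame, the expected photon image is
#' the background haze plus Gaussian spots whose peak photon count is
#' `brightness * signal / frames_per_polarization`; photon counts are
#' Poisson-sampled, scaled by the camera gain, Gaussian read noise is added,
#' the camera offset is added and values are clipped to the bit depth. With
#' `noise = FALSE` the expected counts are returned unrounded.
#'
#' The same scene (including its seed) renders bit-identically.
#'
#' @param scene A [scene_spec()].
#' @param optics An [optical_config()].
#' @param camera A [camera_model()].
#' @param noise Simulate shot and read noise (default `TRUE`).
#' @return A list with `stack` (class `frame_stack`: `frames` list of
#'   matrices, `pol_sequence`, `exposure_ms`, `frame_interval_ms`) and
#'   `truth`, a tibble with one row per NPC (`npc_id`, `x_px`, `y_px`,
#'   `theta_d_deg`, `wobble_half_angle_deg`, `brightness`, `true_p_peak`,
#'   `true_s_peak`, `true_ps_ratio`; peaks are noise-free background-free
#'   counts in the summed images).
#' @export
render_sequence <- function(scene, optics = optical_config(),
                            camera = camera_model(), noise = TRUE) {
  stopifnot(inherits(scene, "scene_spec"), inherits(optics, "optical_config"),
            inherits(camera, "camera_model"))
  field_p <- evanescent_field(optics, "p")
  field_s <- evanescent_field(optics, "s")
  h <- scene$image_shape_px[1]; w <- scene$image_shape_px[2]
  m <- scene$n_frames / 2
  cond <- scene$condition
  gain <- camera$counts_per_photon

  withr::with_seed(scene$seed, {
    pos <- sample_positions(scene$nuclear_roi, scene$n_npcs,
                            scene$min_separation_px, scene$image_shape_px)
    n <- nrow(pos)
    theta <- cond$ensemble$polar_angle_deg +
      stats::rnorm(n, 0, cond$theta_sd_deg)
    theta <- pmin(180, pmax(0, theta))
    bright <- cond$ensemble$brightness *
      if (cond$brightness_cv > 0) {
        sdlog <- sqrt(log(1 + cond$brightness_cv^2))
        stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      } else rep(1, n)

    c2 <- mean_cos2_z(theta, cond$ensemble$wobble_half_angle_deg)
    sig_p <- field_p$ix * (1 - c2) + field_p$iz * c2
    sig_s <- field_s$ix * (1 - c2) + field_s$iz * c2

    # expected photons per frame; background split across frames of one pol
    mean_p <- matrix(scene$background_photon_level / m, h, w)
    mean_s <- mean_p
    for (i in seq_len(n)) {
      mean_p <- add_gaussian_spot(mean_p, pos$x_px[i], pos$y_px[i],
                                  bright[i] * sig_p[i] / m,
                                  scene$psf_sigma_px)
      mean_s <- add_gaussian_spot(mean_s, pos$x_px[i], pos$y_px[i],
                                  bright[i] * sig_s[i] / m,
                                  scene$psf_sigma_px)
    }

    max_dn <- 2^camera$bit_depth - 1
    pol_sequence <- rep(c("p", "s"), m)
    frames <- vector("list", scene$n_frames)
    for (k in seq_len(scene$n_frames)) {
      mu <- if (pol_sequence[k] == "p") mean_p else mean_s
      if (noise) {
        counts <- gain * matrix(stats::rpois(h * w, mu), h, w) +
          matrix(stats::rnorm(h * w, 0, camera$read_noise_counts), h, w) +
          camera$offset_counts
        counts <- round(counts)
      } else {
        counts <- gain * mu + camera$offset_counts
      }
      frames[[k]] <- pmin(pmax(counts, 0), max_dn)
    }
  })

  truth <- tibble::tibble(
    npc_id = seq_len(nrow(pos)),
    x_px = pos$x_px, y_px = pos$y_px,
    theta_d_deg = theta,
    wobble_half_angle_deg = cond$ensemble$wobble_half_angle_deg,
    brightness = bright,
    true_p_peak = gain * bright * sig_p,
    true_s_peak = gain * bright * sig_s,
    true_ps_ratio = sig_p / sig_s,
    condition = cond$label)

  stack <- structure(
    list(frames = frames, pol_sequence = pol_sequence,
         exposure_ms = 5, frame_interval_ms = 15),
    class = "frame_stack")
  list(stack = stack, truth = truth)
}

#' Write a rendered dataset to disk
#'
#' Writes `stack.tif` (16-bit multi-page TIFF, one page per frame),
#' `meta.json` (polarization sequence, exposure, camera, optics, seed) and
#' `ground_truth.csv` into `dir`.
#'
#' @param dataset A list as returned by [render_sequence()].
#' @param dir Output directory (created if needed).
#' @param scene,optics,camera The objects used to render, recorded in the
#'   sidecar metadata.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, scene, optics = optical_config(),
                          camera = camera_model()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  max_dn <- 2^camera$bit_depth - 1
  pages <- lapply(dataset$stack$frames, function(f) round(f) / max_dn)
  tiff::writeTIFF(pages, file.path(dir, "stack.tif"),
                  bits.per.sample = 16, compression = "none")
  meta <- list(
    pol_sequence = dataset$stack$pol_sequence,
    exposure_ms = dataset$stack$exposure_ms,
    frame_interval_ms = dataset$stack$frame_interval_ms,
    camera = unclass(camera),
    optics = unclass(optics),
    seed = scene$seed,
    condition = scene$condition$label)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(dataset$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `stack.tif` and `meta.json`.
#' @return A list with `stack` (class `frame_stack`), `meta`, and `truth`
#'   (tibble, or `NULL` if no ground-truth file is present).
#' @export
read_dataset <- function(dir) {
  tif <- file.path(dir, "stack.tif")
  mj <- file.path(dir, "meta.json")
  if (!file.exists(tif)) stop("missing file: ", tif, call. = FALSE)
  if (!file.exists(mj)) stop("missing metadata sidecar: ", mj, call. = FALSE)
  meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  for (field in c("pol_sequence", "camera")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("metadata %s is missing field '%s'", mj, field),
           call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(tif, all = TRUE)
  max_dn <- 2^meta$camera$bit_depth - 1
  frames <- lapply(pages, function(p) round(p * max_dn))
  if (length(frames) != length(meta$pol_sequence)) {
    stop("frame count does not match pol_sequence length", call. = FALSE)
  }
  stack <- structure(
    list(frames = frames, pol_sequence = meta$pol_sequence,
         exposure_ms = meta$exposure_ms,
         frame_interval_ms = meta$frame_interval_ms),
    class = "frame_stack")
  tr <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(tr)) {
    readr::read_csv(tr, show_col_types = FALSE)
  } else NULL
  list(stack = stack, meta = meta, truth = truth)
}

#' Render a control/perturbed condition pair
#'
#' Emulates a transport-perturbation experiment as a pure orientation-shift
#' scenario: renders a control dataset and a perturbed dataset identical
#' except that the perturbed condition's mean dipole polar angle is shifted
#' by `delta_theta_deg` (independent noise in each). Shifted angles falling
#' outside `[0, 180]` are clamped with a warning recorded in the manifest.
#'
#' @param base A [scene_spec()] describing the control scene.
#' @param delta_theta_deg Polar-angle shift applied to the perturbed
#'   condition, degrees.
#' @param seeds Integer vector of two seeds (control, perturbed).
#' @param optics,camera Acquisition models shared by both datasets.
#' @param out_dir If non-`NULL`, write `control/` and `perturbed/` dataset
#'   directories plus `manifest.json` under this directory.
#' @return A list with `control`, `perturbed` (each as returned by
#'   [render_sequence()]) and `manifest`.
#' @export
generate_condition_pair <- function(base, delta_theta_deg,
                                    seeds = c(base$seed, base$seed + 1),
                                    optics = optical_config(),
                                    camera = camera_model(),
                                    out_dir = NULL) {
  stopifnot(inherits(base, "scene_spec"), length(seeds) == 2)
  ctrl_scene <- base
  ctrl_scene$seed <- as.integer(seeds[1])
  ctrl_scene$condition$label <- "control"

  ens <- base$condition$ensemble
  new_theta <- ens$polar_angle_deg + delta_theta_deg
  clamped <- new_theta < 0 || new_theta > 180
  if (clamped) {
    warning("shifted polar angle clamped to [0, 180] degrees", call. = FALSE)
    new_theta <- min(180, max(0, new_theta))
  }
  pert_scene <- base
  pert_scene$seed <- as.integer(seeds[2])
  pert_scene$condition$label <- "perturbed"
  pert_scene$condition$ensemble$polar_angle_deg <- new_theta

  control <- render_sequence(ctrl_scene, optics, camera)
  perturbed <- render_sequence(pert_scene, optics, camera)

  manifest <- list(
    conditions = c("control", "perturbed"),
    seeds = as.integer(seeds),
    delta_theta_deg = delta_theta_deg,
    control_theta_deg = ens$polar_angle_deg,
    perturbed_theta_deg = new_theta,
    clamped = clamped)

  if (!is.null(out_dir)) {
    write_dataset(control, file.path(out_dir, "control"), ctrl_scene,
                  optics, camera)
    write_dataset(perturbed, file.path(out_dir, "perturbed"), pert_scene,
                  optics, camera)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(control = control, perturbed = perturbed, manifest = manifest)
}
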