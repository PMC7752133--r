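# Automated punctum quantification: per-timepoint frame summing, camera
# background subtraction, ROI-restricted Laplacian-of-Gaussian detection on
# a top-hat-filtered image, dual-polarization Gaussian-fit quality control,
# and the max-pixel p:s ratio per punctum.

#' Analysis configuration for punctum quantification
#'
#' @param camera_offset_counts Camera offset per frame subtracted from the
#'   summed images (scaled by the number of frames summed).
#' @param roi Nuclear [roi_ellipse()]/[roi_polygon()] restricting detection;
#'   `NULL` uses the whole image.
#' @param log_sigma_px Detection scale of the Laplacian-of-Gaussian filter
#'   (match to the PSF sd).
#' @param detection_threshold Minimum scale-normalized LoG response
#'   (counts) for a candidate.
#' @param tophat_radius_px Radius of the disc structuring element of the
#'   white top-hat background flattening.
#' @param fit_window_px Half-width of the square crop fitted around each
#'   candidate; must be at least `3 * log_sigma_px`.
#' @param fit_r2_min Minimum Gaussian-fit R^2 for acceptance.
#' @param fit_sigma_bounds_px Acceptable fitted widths `(lo, hi)`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(camera_offset_counts = 100, roi = NULL,
                            log_sigma_px = 1.3, detection_threshold = 20,
                            tophat_radius_px = 5, fit_window_px = 4,
                            fit_r2_min = 0.5,
                            fit_sigma_bounds_px = c(0.5, 3)) {
  stopifnot(camera_offset_counts >= 0, log_sigma_px > 0,
            detection_threshold >= 0, tophat_radius_px >= 1,
            length(fit_sigma_bounds_px) == 2,
            fit_sigma_bounds_px[1] < fit_sigma_bounds_px[2])
  if (fit_window_px < 3 * log_sigma_px) {
    stop("fit_window_px must be at least 3 * log_sigma_px", call. = FALSE)
  }
  if (!is.null(roi)) stopifnot(inherits(roi, "roi"))
  structure(
    list(camera_offset_counts = camera_offset_counts, roi = roi,
         log_sigma_px = log_sigma_px,
         detection_threshold = detection_threshold,
         tophat_radius_px = tophat_radius_px,
         fit_window_px = as.integer(fit_window_px),
         fit_r2_min = fit_r2_min,
         fit_sigma_bounds_px = fit_sigma_bounds_px),
    class = "analysis_config")
}

#' Sum alternating-polarization frames into one p and one s image
#'
#' Pixelwise sums of all frames carrying each polarization label; no
#' normalization is applied. For a 20-frame alternating stack each summed
#' image combines 10 frames.
#'
#' @param stack A `frame_stack` (see [render_sequence()]).
#' @return An object of class `timepoint_pair`: `p_image`, `s_image`,
#'   `frames_summed_per_pol`.
#' @export
sum_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  labels <- stack$pol_sequence
  if (length(labels) != length(stack$frames)) {
    stop("pol_sequence must label every frame", call. = FALSE)
  }
  if (!all(labels %in% c("p", "s"))) {
    stop("pol_sequence labels must be 'p' or 's'", call. = FALSE)
  }
  n_p <- sum(labels == "p"); n_s <- sum(labels == "s")
  if (n_p == 0 || n_s == 0) {
    stop("need at least one frame per polarization", call. = FALSE)
  }
  if (n_p != n_s) {
    warning("unequal p and s frame counts; summed images are not comparable frame-for-frame",
            call. = FALSE)
  }
  p_image <- Reduce(`+`, stack$frames[labels == "p"])
  s_image <- Reduce(`+`, stack$frames[labels == "s"])
  structure(
    list(p_image = p_image, s_image = s_image,
         frames_summed_per_pol = n_p, bg_subtracted = FALSE),
    class = "timepoint_pair")
}

#' Subtract the camera background from a summed image pair
#'
#' Subtracts `camera_offset_counts * frames_summed_per_pol` from every pixel
#' of both summed images, clipping at zero. Applying it twice to the same
#' pair is an error: the pipeline tracks subtraction state.
#'
#' @param pair A [sum_frames()] result.
#' @param camera_offset_counts Per-frame camera offset (>= 0).
#' @param frames_summed_per_pol Number of frames summed per polarization;
#'   defaults to the value recorded in `pair`.
#' @return The pair with background removed (`bg_subtracted = TRUE`).
#' @export
subtract_camera_background <- function(pair, camera_offset_counts,
                                       frames_summed_per_pol =
                                         pair$frames_summed_per_pol) {
  stopifnot(inherits(pair, "timepoint_pair"), camera_offset_counts >= 0)
  if (isTRUE(pair$bg_subtracted)) {
    stop("camera background has already been subtracted from this pair",
         call. = FALSE)
  }
  total <- camera_offset_counts * frames_summed_per_pol
  pair$p_image <- pmax(pair$p_image - total, 0)
  pair$s_image <- pmax(pair$s_image - total, 0)
  pair$bg_subtracted <- TRUE
  pair
}

#' Discretized scale-normalized Laplacian-of-Gaussian kernel
#'
#' Returns `-sigma^2 * LoG` sampled on an odd square grid spanning
#' +/- `ceiling(4 sigma)` pixels, adjusted to zero sum so that constant
#' images give an exactly zero response. The sign is flipped so that bright
#' blobs of width ~sigma yield positive response maxima.
#'
#' @param sigma Kernel scale in pixels.
#' @return Odd-sized square matrix.
#' @export
log_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  ax <- (-half):half
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  k <- -sigma^2 * (r2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)
}

#' Scale-normalized LoG response map
#'
#' Correlates the image with [log_kernel()] using replicate padding at the
#' borders.
#'
#' @param img Numeric matrix.
#' @param sigma Detection scale in pixels.
#' @return Response matrix of the same size.
#' @export
log_response <- function(img, sigma) {
  EBImage::filter2(img, log_kernel(sigma), boundary = "replicate")
}

# local maxima of `resp` (strictly greater than any 8-neighbor, >= on ties
# resolved later by the merge step) above `threshold`
local_maxima <- function(resp, threshold) {
  h <- nrow(resp); w <- ncol(resp)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- resp
  is_max <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    is_max <- is_max & (resp >= nb)
  }
  idx <- which(is_max & resp > threshold, arr.ind = TRUE)
  tibble::tibble(row = as.vector(idx[, 1]), col = as.vector(idx[, 2]),
                 response = resp[idx])
}

#' Detect candidate puncta in a summed image pair
#'
#' Builds the detection image as the sum of the background-subtracted p and
#' s images (maximizing SNR and avoiding polarization bias), flattens it
#' with a white top-hat of radius `tophat_radius_px`, computes the
#' scale-normalized LoG response at `log_sigma_px`, and keeps local maxima
#' above `detection_threshold` inside the ROI. Candidates closer than
#' `2 * log_sigma_px` are merged keeping the stronger response (ties broken
#' by lexicographic row, column); candidates within `fit_window_px` of the
#' image edge are flagged `edge = TRUE`.
#'
#' @param pair Background-subtracted [sum_frames()] result.
#' @param config An [analysis_config()].
#' @return Tibble of candidates: `x_px`, `y_px` (0-based), `scale`,
#'   `response`, `edge`.
#' @export
detect_puncta <- function(pair, config) {
  stopifnot(inherits(pair, "timepoint_pair"),
            inherits(config, "analysis_config"))
  if (!isTRUE(pair$bg_subtracted)) {
    stop("detect_puncta requires background-subtracted images", call. = FALSE)
  }
  det <- pair$p_image + pair$s_image
  h <- nrow(det); w <- ncol(det)
  roi <- config$roi
  if (!is.null(roi)) {
    mask <- roi_mask(roi, c(h, w))
    if (!any(mask)) stop("ROI covers no pixels", call. = FALSE)
  }
  brush <- EBImage::makeBrush(2 * config$tophat_radius_px + 1, shape = "disc")
  flat <- EBImage::whiteTopHat(det, brush)
  resp <- log_response(flat, config$log_sigma_px)
  cand <- local_maxima(resp, config$detection_threshold)
  if (!is.null(roi) && nrow(cand) > 0) {
    keep <- in_roi(roi, cand$col - 1, cand$row - 1)
    cand <- cand[keep, , drop = FALSE]
  }
  # merge near-duplicates, strongest response wins; lexicographic tie-break
  cand <- cand[order(-cand$response, cand$row, cand$col), , drop = FALSE]
  if (nrow(cand) > 1) {
    keep <- rep(TRUE, nrow(cand))
    min2 <- (2 * config$log_sigma_px)^2
    for (i in seq_len(nrow(cand))[-1]) {
      prev <- which(keep[seq_len(i - 1)])
      d2 <- (cand$row[prev] - cand$row[i])^2 + (cand$col[prev] - cand$col[i])^2
      if (any(d2 < min2)) keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  fw <- config$fit_window_px
  edge <- cand$row <= fw | cand$row > h - fw | cand$col <= fw | cand$col > w - fw
  tibble::tibble(x_px = cand$col - 1, y_px = cand$row - 1,
                 scale = config$log_sigma_px,
                 response = cand$response, edge = edge)
}

#' Fit a 2-D Gaussian with constant offset to an image crop
#'
#' Least-squares fit of `offset + A * exp(-((x-x0)^2+(y-y0)^2)/(2 sigma^2))`
#' by Levenberg-Marquardt. Coordinates are 0-based pixels of the full image.
#'
#' @param crop Numeric matrix.
#' @param x_off,y_off 0-based coordinates of `crop[1, 1]` in the full image.
#' @return List: `amplitude`, `x0`, `y0`, `sigma`, `offset`, `r2`,
#'   `converged`.
#' @export
fit_gaussian2d <- function(crop, x_off = 0, y_off = 0) {
  h <- nrow(crop); w <- ncol(crop)
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  z <- as.vector(crop)
  peak <- which.max(z)
  p0 <- c(amp = max(z) - min(z), x0 = xs[peak], y0 = ys[peak],
          sigma = max(1, (w - 1) / 8), off = min(z))
  resid_fun <- function(p) {
    p["off"] + p["amp"] *
      exp(-((xs - p["x0"])^2 + (ys - p["y0"])^2) / (2 * p["sigma"]^2)) - z
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, fn = resid_fun,
      lower = c(-Inf, -1, -1, 0.1, -Inf),
      upper = c(Inf, w, h, w, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(amplitude = NA_real_, x0 = NA_real_, y0 = NA_real_,
                sigma = NA_real_, offset = NA_real_, r2 = NA_real_,
                converged = FALSE))
  }
  p <- fit$par
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((z - mean(z))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(amplitude = unname(p["amp"]), x0 = unname(p["x0"]) + x_off,
       y0 = unname(p["y0"]) + y_off, sigma = unname(p["sigma"]),
       offset = unname(p["off"]), r2 = r2,
       converged = fit$info %in% 1:3)
}

fit_one_pol <- function(img, row, col, config) {
  fw <- config$fit_window_px
  crop <- img[(row - fw):(row + fw), (col - fw):(col + fw)]
  fit_gaussian2d(crop, x_off = col - 1 - fw, y_off = row - 1 - fw)
}

fit_ok <- function(fit, config) {
  isTRUE(fit$converged) && !is.na(fit$amplitude) && fit$amplitude > 0 &&
    fit$sigma >= config$fit_sigma_bounds_px[1] &&
    fit$sigma <= config$fit_sigma_bounds_px[2] &&
    !is.na(fit$r2) && fit$r2 >= config$fit_r2_min
}

#' Gaussian-fit quality control of detected candidates
#'
#' Fits a 2-D Gaussian with constant offset independently to the p and s
#' crops (side `2 * fit_window_px + 1`) of each candidate. A fit succeeds if
#' the optimizer converges, the amplitude is positive, the fitted width lies
#' within `fit_sigma_bounds_px` and R^2 is at least `fit_r2_min`. Failure on
#' either polarization rejects the punctum (reasons `fit_failed_p` /
#' `fit_failed_s`); edge candidates are rejected with reason `edge` and are
#' not fitted.
#'
#' @param pair Background-subtracted [sum_frames()] result.
#' @param candidates Tibble from [detect_puncta()].
#' @param config An [analysis_config()].
#' @return Tibble of punctum measurements with fit diagnostics and
#'   `accepted` / `reject_reason` columns; intensity columns are filled by
#'   [measure_ps()].
#' @export
fit_and_filter <- function(pair, candidates, config) {
  stopifnot(inherits(pair, "timepoint_pair"),
            inherits(config, "analysis_config"))
  n <- nrow(candidates)
  empty_fit <- list(amplitude = NA_real_, x0 = NA_real_, y0 = NA_real_,
                    sigma = NA_real_, offset = NA_real_, r2 = NA_real_,
                    converged = FALSE)
  rows <- purrr::map(seq_len(n), function(i) {
    cand <- candidates[i, ]
    if (cand$edge) {
      return(list(p = empty_fit, s = empty_fit, accepted = FALSE,
                  reason = "edge"))
    }
    row <- cand$y_px + 1; col <- cand$x_px + 1
    fp <- fit_one_pol(pair$p_image, row, col, config)
    fs <- fit_one_pol(pair$s_image, row, col, config)
    if (!fit_ok(fp, config)) {
      list(p = fp, s = fs, accepted = FALSE, reason = "fit_failed_p")
    } else if (!fit_ok(fs, config)) {
      list(p = fp, s = fs, accepted = FALSE, reason = "fit_failed_s")
    } else {
      list(p = fp, s = fs, accepted = TRUE, reason = "none")
    }
  })
  fit_col <- function(which_pol, field) {
    purrr::map_dbl(rows, function(r) r[[which_pol]][[field]] %||% NA_real_)
  }
  tibble::tibble(
    punctum_id = seq_len(n),
    x_px = candidates$x_px, y_px = candidates$y_px,
    response = candidates$response,
    p_amplitude = fit_col("p", "amplitude"),
    p_x0 = fit_col("p", "x0"), p_y0 = fit_col("p", "y0"),
    p_sigma = fit_col("p", "sigma"), p_r2 = fit_col("p", "r2"),
    s_amplitude = fit_col("s", "amplitude"),
    s_x0 = fit_col("s", "x0"), s_y0 = fit_col("s", "y0"),
    s_sigma = fit_col("s", "sigma"), s_r2 = fit_col("s", "r2"),
    accepted = purrr::map_lgl(rows, "accepted"),
    reject_reason = purrr::map_chr(rows, "reason"),
    p_max = NA_real_, s_max = NA_real_, ps_ratio = NA_real_)
}

#' Extract max-pixel intensities and the p:s ratio per punctum
#'
#' Intensities are taken from the summed, camera-background-subtracted (but
#' not top-hat-filtered) images: the maximum pixel within the fit window at
#' each polarization. For accepted puncta with positive s intensity,
#' `ps_ratio = p_max / s_max`; a non-positive s maximum rejects the punctum
#' with reason `s_nonpositive`.
#'
#' @param pair Background-subtracted [sum_frames()] result.
#' @param measurements Tibble from [fit_and_filter()].
#' @param config An [analysis_config()].
#' @return The measurements tibble with `p_max`, `s_max`, `ps_ratio` filled.
#' @export
measure_ps <- function(pair, measurements, config) {
  stopifnot(inherits(pair, "timepoint_pair"),
            inherits(config, "analysis_config"))
  fw <- config$fit_window_px
  for (i in seq_len(nrow(measurements))) {
    if (identical(measurements$reject_reason[i], "edge")) next
    row <- measurements$y_px[i] + 1; col <- measurements$x_px[i] + 1
    rows <- (row - fw):(row + fw); cols <- (col - fw):(col + fw)
    p_max <- max(pair$p_image[rows, cols])
    s_max <- max(pair$s_image[rows, cols])
    measurements$p_max[i] <- p_max
    measurements$s_max[i] <- s_max
    if (measurements$accepted[i]) {
      if (s_max <= 0) {
        measurements$accepted[i] <- FALSE
        measurements$reject_reason[i] <- "s_nonpositive"
      } else {
        measurements$ps_ratio[i] <- p_max / s_max
      }
    }
  }
  measurements
}
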