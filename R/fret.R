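# Acceptor-photobleaching FRET: donor intensity is measured before and
# after destroying the acceptor; de-quenching of the donor reports energy
# transfer. Efficiency per NPC is (I_post - I_pre) / I_post from max-pixel
# donor intensities.

#' Pre-/post-bleach donor image pair
#'
#' @param donor_pre,donor_post Donor images (counts) of identical shape.
#' @param bleach_metadata Optional informational record of the bleach
#'   (laser, duration).
#' @return An object of class `fret_image_pair`.
#' @export
fret_image_pair <- function(donor_pre, donor_post, bleach_metadata = NULL) {
  stopifnot(is.matrix(donor_pre), is.matrix(donor_post),
            all(dim(donor_pre) == dim(donor_post)))
  structure(
    list(donor_pre = donor_pre, donor_post = donor_post,
         bleach_metadata = bleach_metadata),
    class = "fret_image_pair")
}

#' Track a spot from the pre-bleach to the post-bleach image
#'
#' Returns the location of the maximum post-bleach donor pixel within
#' `search_radius_px` of the pre-bleach position. Ties are broken by the
#' smallest displacement, then lexicographically (row, column); a flat
#' window therefore returns the pre-bleach position.
#'
#' @param pre_xy Numeric `(x, y)` 0-based pixel position in the pre image.
#' @param donor_post Post-bleach donor image.
#' @param search_radius_px Search radius in pixels (>= 1).
#' @return Numeric `(x, y)` 0-based position of the tracked spot.
#' @export
track_spot <- function(pre_xy, donor_post, search_radius_px = 5) {
  stopifnot(length(pre_xy) == 2, search_radius_px >= 1)
  h <- nrow(donor_post); w <- ncol(donor_post)
  col0 <- round(pre_xy[1]) + 1; row0 <- round(pre_xy[2]) + 1
  r <- round(search_radius_px)
  rows <- max(1, row0 - r):min(h, row0 + r)
  cols <- max(1, col0 - r):min(w, col0 + r)
  if (row0 + r < 1 || row0 - r > h || col0 + r < 1 || col0 - r > w) {
    stop("search window lies entirely outside the image", call. = FALSE)
  }
  win <- donor_post[rows, cols, drop = FALSE]
  best <- which(win == max(win), arr.ind = TRUE)
  cand_row <- rows[best[, 1]]; cand_col <- cols[best[, 2]]
  d2 <- (cand_row - row0)^2 + (cand_col - col0)^2
  ord <- order(d2, cand_row, cand_col)
  c(x = cand_col[ord[1]] - 1, y = cand_row[ord[1]] - 1)
}

#' Apparent FRET efficiency from pre-/post-bleach donor intensities
#'
#' `efficiency = (i_post - i_pre) / i_post`. Negative values are permitted
#' (no detectable FRET plus noise) and flagged via the attached
#' `negative` attribute consumed by [run_fret()].
#'
#' @param i_pre,i_post Donor max-pixel intensities (counts,
#'   background-subtracted); `i_post` must be positive.
#' @return Dimensionless efficiency (at most 1).
#' @export
#' @examples
#' fret_efficiency(80, 100)  # 0.2
fret_efficiency <- function(i_pre, i_post) {
  if (any(i_post <= 0)) {
    stop("post-bleach intensity nonpositive", call. = FALSE)
  }
  (i_post - i_pre) / i_post
}

#' Configuration for FRET quantification
#'
#' @param camera_offset_counts Camera offset subtracted from both donor
#'   images before intensities are extracted (the efficiency formula is
#'   biased toward zero on offset-containing counts).
#' @param window_px Half-width of the max-pixel window around each spot.
#' @param search_radius_px Tracking search radius.
#' @return An object of class `fret_config`.
#' @export
fret_config <- function(camera_offset_counts = 100, window_px = 3,
                        search_radius_px = 5) {
  stopifnot(camera_offset_counts >= 0, window_px >= 1, search_radius_px >= 1)
  structure(
    list(camera_offset_counts = camera_offset_counts,
         window_px = as.integer(window_px),
         search_radius_px = search_radius_px),
    class = "fret_config")
}

max_in_window <- function(img, x, y, half) {
  h <- nrow(img); w <- ncol(img)
  rows <- max(1, round(y) + 1 - half):min(h, round(y) + 1 + half)
  cols <- max(1, round(x) + 1 - half):min(w, round(x) + 1 + half)
  m <- which(img[rows, cols, drop = FALSE] ==
               max(img[rows, cols, drop = FALSE]), arr.ind = TRUE)[1, ]
  list(value = img[rows[m[1]], cols[m[2]]],
       x = cols[m[2]] - 1, y = rows[m[1]] - 1)
}

#' Quantify FRET efficiency for a list of spots
#'
#' Per spot: the pre-bleach donor max pixel in a window at `pre_xy` gives
#' `i_pre`; the spot is tracked to the post-bleach image ([track_spot()])
#' and the post-bleach max pixel gives `i_post`; the apparent efficiency is
#' `(i_post - i_pre) / i_post`. Camera background is subtracted from both
#' images first. Per-spot failures are recorded in the `status` column
#' rather than aborting the run.
#'
#' @param pair A [fret_image_pair()].
#' @param spots Tibble/data.frame with columns `x_px`, `y_px` (0-based
#'   pre-bleach positions; e.g. a manual list or [detect_puncta()] output).
#' @param config A [fret_config()].
#' @param out_dir Optional directory; writes `fret.csv`.
#' @return Tibble: `npc_id`, `pre_x_px`, `pre_y_px`, `post_x_px`,
#'   `post_y_px`, `i_pre`, `i_post`, `efficiency`, `status`
#'   (`ok` / `negative` / `post_nonpositive`).
#' @export
run_fret <- function(pair, spots, config = fret_config(), out_dir = NULL) {
  stopifnot(inherits(pair, "fret_image_pair"),
            all(c("x_px", "y_px") %in% names(spots)))
  off <- config$camera_offset_counts
  pre <- pmax(pair$donor_pre - off, 0)
  post <- pmax(pair$donor_post - off, 0)
  n <- nrow(spots)
  res <- tibble::tibble(
    npc_id = seq_len(n),
    pre_x_px = NA_real_, pre_y_px = NA_real_,
    post_x_px = NA_real_, post_y_px = NA_real_,
    i_pre = NA_real_, i_post = NA_real_,
    efficiency = NA_real_, status = NA_character_)
  for (i in seq_len(n)) {
    pre_peak <- max_in_window(pre, spots$x_px[i], spots$y_px[i],
                              config$window_px)
    res$pre_x_px[i] <- pre_peak$x; res$pre_y_px[i] <- pre_peak$y
    res$i_pre[i] <- pre_peak$value
    post_xy <- track_spot(c(spots$x_px[i], spots$y_px[i]), post,
                          config$search_radius_px)
    post_peak <- max_in_window(post, post_xy[1], post_xy[2],
                               config$window_px)
    res$post_x_px[i] <- post_peak$x; res$post_y_px[i] <- post_peak$y
    res$i_post[i] <- post_peak$value
    if (post_peak$value <= 0) {
      res$status[i] <- "post_nonpositive"
    } else {
      eff <- fret_efficiency(pre_peak$value, post_peak$value)
      res$efficiency[i] <- eff
      res$status[i] <- if (eff < 0) "negative" else "ok"
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(res, file.path(out_dir, "fret.csv"))
  }
  res
}

#' Simulate a pre-/post-bleach donor image pair
#'
#' Renders `n_spots` donor puncta; the post-bleach image carries the full
#' donor brightness while the pre-bleach donor is quenched by the FRET
#' efficiency (`pre = (1 - efficiency) * post` pattern). Shot noise, read
#' noise and the camera offset follow the camera model. With
#' `bleach_fraction < 1` only that fraction of the quenching is released,
#' emulating incomplete acceptor bleaching.
#'
#' @param n_spots Number of spots.
#' @param efficiency True FRET efficiency in `[0, 1)`.
#' @param brightness Post-bleach peak photon count per spot.
#' @param image_shape_px Image size `(height, width)`.
#' @param psf_sigma_px PSF sd, pixels.
#' @param background_photon_level Out-of-spot haze photons per pixel.
#' @param camera A [camera_model()].
#' @param seed RNG seed.
#' @param noise Simulate noise (default `TRUE`).
#' @param bleach_fraction Fraction of acceptor actually bleached.
#' @param min_separation_px Minimum spot separation.
#' @return List: `pair` ([fret_image_pair()]), `spots` (tibble with
#'   0-based `x_px`, `y_px` and per-spot `true_efficiency`).
#' @export
simulate_fret_pair <- function(n_spots = 100, efficiency = 0.25,
                               brightness = 400,
                               image_shape_px = c(160, 160),
                               psf_sigma_px = 1.3,
                               background_photon_level = 5,
                               camera = camera_model(), seed = 1,
                               noise = TRUE, bleach_fraction = 1,
                               min_separation_px = 8) {
  stopifnot(efficiency >= 0, efficiency < 1,
            bleach_fraction > 0, bleach_fraction <= 1)
  h <- image_shape_px[1]; w <- image_shape_px[2]
  roi <- default_nuclear_roi(image_shape_px)
  gain <- camera$counts_per_photon
  max_dn <- 2^camera$bit_depth - 1
  withr::with_seed(seed, {
    pos <- sample_positions(roi, n_spots, min_separation_px, image_shape_px)
    mean_post_full <- matrix(background_photon_level, h, w)
    for (i in seq_len(n_spots)) {
      mean_post_full <- add_gaussian_spot(mean_post_full, pos$x_px[i],
                                          pos$y_px[i], brightness,
                                          psf_sigma_px)
    }
    bg <- matrix(background_photon_level, h, w)
    spot_part <- mean_post_full - bg
    mean_pre <- bg + (1 - efficiency) * spot_part
    # donor recovered after bleaching a fraction of the acceptors
    mean_post <- bg +
      (1 - efficiency + bleach_fraction * efficiency) * spot_part
    digitize <- function(mu) {
      if (noise) {
        counts <- gain * matrix(stats::rpois(h * w, mu), h, w) +
          matrix(stats::rnorm(h * w, 0, camera$read_noise_counts), h, w) +
          camera$offset_counts
        counts <- round(counts)
      } else {
        counts <- gain * mu + camera$offset_counts
      }
      pmin(pmax(counts, 0), max_dn)
    }
    donor_pre <- digitize(mean_pre)
    donor_post <- digitize(mean_post)
  })
  true_eff <- 1 - (1 - efficiency) /
    (1 - efficiency + bleach_fraction * efficiency)
  list(
    pair = fret_image_pair(donor_pre, donor_post,
                           bleach_metadata = list(simulated = TRUE,
                                                  seed = seed)),
    spots = tibble::tibble(npc_id = seq_len(n_spots),
                           x_px = pos$x_px, y_px = pos$y_px,
                           true_efficiency = true_eff))
}
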