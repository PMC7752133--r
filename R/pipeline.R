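# End-to-end composition of the quantification stages, plus helpers that
# pair measurements with simulation ground truth.

#' Quantify one timepoint stack in memory
#'
#' Composes [sum_frames()], [subtract_camera_background()],
#' [detect_puncta()], [fit_and_filter()] and [measure_ps()].
#'
#' @param stack A `frame_stack`.
#' @param config An [analysis_config()].
#' @return Punctum measurement tibble.
#' @export
quantify_stack <- function(stack, config) {
  pair <- sum_frames(stack)
  pair <- subtract_camera_background(pair, config$camera_offset_counts)
  cand <- detect_puncta(pair, config)
  meas <- fit_and_filter(pair, cand, config)
  measure_ps(pair, meas, config)
}

#' Run the full quantification pipeline on a dataset
#'
#' Reads a dataset directory (multi-page TIFF plus JSON sidecar, as written
#' by [write_dataset()]) or takes an in-memory `frame_stack`, runs the four
#' quantification stages in order, and returns the punctum table with
#' provenance columns (`source`, `config_hash`). If `out_dir` is given,
#' writes `puncta.csv` and `run.log` (detection count, acceptance count and
#' the rejection breakdown).
#'
#' @param input Dataset directory path or a `frame_stack`.
#' @param config An [analysis_config()]. When reading a dataset directory
#'   whose metadata records a camera offset, the metadata value is used
#'   unless the config was built with a different explicit offset.
#' @param out_dir Optional output directory.
#' @return Punctum measurement tibble.
#' @export
run_pipeline <- function(input, config = analysis_config(), out_dir = NULL) {
  if (is.character(input)) {
    ds <- read_dataset(input)
    stack <- ds$stack
    meta_offset <- ds$meta$camera$offset_counts
    if (!is.null(meta_offset)) config$camera_offset_counts <- meta_offset
    src <- normalizePath(input)
  } else if (inherits(input, "frame_stack")) {
    stack <- input
    src <- "<in-memory stack>"
  } else {
    stop("input must be a dataset directory path or a frame_stack",
         call. = FALSE)
  }
  meas <- quantify_stack(stack, config)
  meas$source <- src
  meas$config_hash <- rlang::hash(unclass(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(meas, file.path(out_dir, "puncta.csv"))
    breakdown <- table(meas$reject_reason[!meas$accepted])
    log_lines <- c(
      sprintf("source: %s", src),
      sprintf("config_hash: %s", meas$config_hash[1] %||% rlang::hash(unclass(config))),
      sprintf("n_detected: %d", nrow(meas)),
      sprintf("n_accepted: %d", sum(meas$accepted)),
      sprintf("rejections: %s",
              if (length(breakdown)) {
                paste(names(breakdown), as.integer(breakdown),
                      sep = "=", collapse = ", ")
              } else "none"),
      "coordinates: x_px = column, y_px = row, 0-based")
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  meas
}

#' Match measurements to simulation ground truth
#'
#' Greedily matches accepted puncta to ground-truth NPCs within
#' `radius_px`, strongest detection first, each NPC used at most once.
#'
#' @param measurements Punctum tibble (e.g. from [quantify_stack()]).
#' @param truth Ground-truth tibble from [render_sequence()].
#' @param radius_px Match radius in pixels.
#' @return `measurements` restricted to accepted rows, with `npc_id`,
#'   `true_ps_ratio`, `true_p_peak`, `true_s_peak`, `theta_d_deg` joined
#'   (`NA` for unmatched/spurious detections).
#' @export
match_to_truth <- function(measurements, truth, radius_px = 2) {
  acc <- dplyr::filter(measurements, .data$accepted)
  acc <- dplyr::arrange(acc, dplyr::desc(.data$response))
  acc$npc_id <- NA_integer_
  used <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(acc))) {
    d2 <- (truth$x_px - acc$x_px[i])^2 + (truth$y_px - acc$y_px[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) == 1 && d2[j] <= radius_px^2) {
      acc$npc_id[i] <- truth$npc_id[j]
      used[j] <- TRUE
    }
  }
  dplyr::left_join(
    acc,
    dplyr::select(truth, "npc_id", "true_ps_ratio", "true_p_peak",
                  "true_s_peak", "theta_d_deg"),
    by = "npc_id")
}

#' Detection performance against ground truth
#'
#' @param measurements Punctum tibble.
#' @param truth Ground-truth tibble.
#' @param radius_px Match radius in pixels.
#' @return One-row tibble: `n_truth`, `n_accepted`, `n_matched`, `recall`,
#'   `spurious_rate` (unmatched accepted detections / accepted detections).
#' @export
detection_performance <- function(measurements, truth, radius_px = 2) {
  matched <- match_to_truth(measurements, truth, radius_px)
  n_matched <- sum(!is.na(matched$npc_id))
  n_acc <- nrow(matched)
  tibble::tibble(
    n_truth = nrow(truth),
    n_accepted = n_acc,
    n_matched = n_matched,
    recall = n_matched / nrow(truth),
    spurious_rate = if (n_acc > 0) (n_acc - n_matched) / n_acc else 0)
}

#' Simulate scenes and quantify them until a target punctum count is reached
#'
#' Renders independent scenes (seeds `seed`, `seed + 1`, ...) under one
#' condition and runs the quantification pipeline on each, pooling accepted,
#' truth-matched puncta until at least `n_puncta` are collected (the paper's
#' per-condition sample is 300 puncta pooled over cells; each scene stands
#' in for one cell's nuclear surface).
#'
#' @param condition A [condition_spec()].
#' @param n_puncta Target number of accepted puncta.
#' @param seed Base seed for the first scene.
#' @param scene_args Named list of overrides passed to [scene_spec()].
#' @param optics,camera Acquisition models.
#' @param config An [analysis_config()]; by default the offset matches the
#'   camera model and the ROI matches the scene.
#' @param max_scenes Safety cap on the number of scenes rendered.
#' @return Tibble of accepted measurements joined with ground truth
#'   (columns as [match_to_truth()], plus `scene` and `condition`), sliced
#'   to the first `n_puncta` rows.
#' @export
simulate_and_quantify <- function(condition, n_puncta = 300, seed = 1,
                                  scene_args = list(),
                                  optics = optical_config(),
                                  camera = camera_model(),
                                  config = NULL, max_scenes = 40) {
  out <- list()
  n_acc <- 0
  scene_i <- 0
  while (n_acc < n_puncta && scene_i < max_scenes) {
    scene_i <- scene_i + 1
    args <- utils::modifyList(
      list(condition = condition, seed = seed + scene_i - 1), scene_args)
    scene <- do.call(scene_spec, args)
    if (is.null(config)) {
      cfg <- analysis_config(camera_offset_counts = camera$offset_counts,
                             roi = scene$nuclear_roi)
    } else {
      cfg <- config
    }
    ds <- render_sequence(scene, optics, camera)
    meas <- quantify_stack(ds$stack, cfg)
    matched <- match_to_truth(meas, ds$truth)
    matched$scene <- scene_i
    matched$condition <- condition$label
    out[[scene_i]] <- matched
    n_acc <- n_acc + nrow(matched)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) < n_puncta) {
    warning(sprintf("collected %d of %d requested puncta", nrow(res),
                    n_puncta), call. = FALSE)
  }
  dplyr::slice_head(res, n = n_puncta)
}
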