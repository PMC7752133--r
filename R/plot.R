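# ggplot2 figures for measurement tables and forward-model curves.

#' Box plot of per-punctum values by condition
#'
#' Boxes span the quartiles with the center bar at the median (no whiskers
#' beyond 1.5 IQR are hidden); points are overlaid with jitter.
#'
#' @param data Punctum tibble with a condition column.
#' @param value,condition Column names.
#' @return A ggplot object.
#' @export
plot_condition_boxes <- function(data, value = "ps_ratio",
                                 condition = "condition") {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[condition]], y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.2, size = 0.6) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_classic()
}

#' Map of detected puncta colored by p:s ratio
#'
#' Reproduces the per-NPC ratio map view: accepted puncta at their detected
#' positions, colored by the p:s ratio.
#'
#' @param measurements Punctum tibble ([quantify_stack()] output).
#' @return A ggplot object.
#' @export
plot_ratio_map <- function(measurements) {
  acc <- dplyr::filter(measurements, .data$accepted)
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                    color = .data$ps_ratio)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_viridis_c(name = "p:s ratio") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_classic()
}

#' Forward-model p:s ratio versus dipole polar angle
#'
#' @param optics An [optical_config()].
#' @param wobble_half_angle_deg One or more wobble half-angles to draw.
#' @param theta_range_deg Polar-angle range (degrees, open at 0 where the
#'   zero-wobble ratio diverges).
#' @return A ggplot object.
#' @export
plot_forward_curve <- function(optics = optical_config(),
                               wobble_half_angle_deg = c(0, 15, 45),
                               theta_range_deg = c(5, 90)) {
  fp <- evanescent_field(optics, "p")
  fs <- evanescent_field(optics, "s")
  grid <- tidyr::expand_grid(
    theta = seq(theta_range_deg[1], theta_range_deg[2], length.out = 120),
    wobble = wobble_half_angle_deg)
  grid$ratio <- purrr::map2_dbl(grid$theta, grid$wobble, function(t, w) {
    predict_ps_ratio(dipole_ensemble(t, wobble_half_angle_deg = w), fp, fs)
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$theta, y = .data$ratio,
                                     color = factor(.data$wobble))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dipole polar angle (deg)", y = "predicted p:s ratio",
                  color = "wobble (deg)") +
    ggplot2::theme_classic()
}

#' @rdname plot_condition_boxes
#' @param object A `pol_comparison` object (plotted as its Tukey adjusted
#'   p-values) — autoplot method.
#' @param ... Unused.
#' @method autoplot pol_comparison
#' @export
autoplot.pol_comparison <- function(object, ...) {
  if (is.null(object$pairwise)) {
    stop("autoplot is available for comparisons with a Tukey table",
         call. = FALSE)
  }
  ggplot2::ggplot(object$pairwise, ggplot2::aes(
    x = .data$pair, y = -log10(pmax(.data$p_adj, 1e-300)))) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = NULL, y = "-log10 adjusted p") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
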