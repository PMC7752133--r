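# broom-style tidiers for comparison and trend objects.

#' Tidy a condition comparison
#'
#' For a t-test, one row with the statistic and p-value; for an ANOVA with
#' a Tukey table, one row per pairwise comparison with the adjusted
#' p-value.
#'
#' @param x A `pol_comparison` from [compare_two()]/[compare_many()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pol_comparison
#' @export
tidy.pol_comparison <- function(x, ...) {
  if (!is.null(x$pairwise)) {
    dplyr::mutate(x$pairwise, test = x$test_name, .before = 1)
  } else {
    tibble::tibble(test = x$test_name, statistic = x$statistic,
                   p_value = x$p_value)
  }
}

#' One-row summary of a condition comparison
#'
#' @param x A `pol_comparison`.
#' @param ... Unused.
#' @return One-row tibble: `test`, `statistic`, `p_value`,
#'   `n_significant_pairs` (NA when no post hoc table exists).
#' @method glance pol_comparison
#' @export
glance.pol_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test_name, statistic = x$statistic, p_value = x$p_value,
    n_significant_pairs = if (!is.null(x$pairwise)) {
      sum(x$pairwise$p_adj < 0.05)
    } else NA_integer_)
}

#' Tidy a spatial-trend result
#'
#' @param x A `spatial_trend` object.
#' @param ... Unused.
#' @return Tibble with one row per axis: `axis`, `slope`, `p_value`.
#' @method tidy spatial_trend
#' @export
tidy.spatial_trend <- function(x, ...) x$trends

#' One-row summary of a spatial-trend result
#'
#' @param x A `spatial_trend` object.
#' @param ... Unused.
#' @return One-row tibble: `uniform`, `alpha`, `min_p_value`.
#' @method glance spatial_trend
#' @export
glance.spatial_trend <- function(x, ...) {
  tibble::tibble(uniform = x$uniform, alpha = x$alpha,
                 min_p_value = min(x$trends$p_value))
}
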