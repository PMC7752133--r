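# Condition-level aggregation and the statistical comparisons used on
# per-punctum p:s ratios and FRET efficiencies: quartile/median summaries,
# Student's t-test, one-way ANOVA with Tukey post hoc, a spatial-uniformity
# regression, and a kernel-density unimodality check.

#' Quartile summary of per-punctum values by condition
#'
#' Median and Tukey hinges (the box-plot convention: hinges of the lower
#' and upper halves, median excluded for odd n), plus value and cell counts.
#'
#' @param data Data frame with one row per punctum.
#' @param value Column of values (p:s ratios or FRET efficiencies);
#'   tidy-selected, default `ps_ratio`.
#' @param condition Optional grouping column (default `condition` if
#'   present).
#' @param cell Optional cell-id column for `n_cells`.
#' @return Tibble: one row per condition with `n_values`, `n_cells`,
#'   `median`, `q1`, `q3`.
#' @export
#' @examples
#' summarize_conditions(tibble::tibble(ps_ratio = 1:5))
summarize_conditions <- function(data, value = "ps_ratio",
                                 condition = if ("condition" %in% names(data))
                                   "condition" else NULL,
                                 cell = NULL) {
  stopifnot(value %in% names(data))
  vals_all <- data[[value]]
  if (length(vals_all) == 0 || any(!is.finite(vals_all))) {
    stop("values must be non-empty and finite", call. = FALSE)
  }
  groups <- if (is.null(condition)) {
    list(`all` = seq_len(nrow(data)))
  } else {
    split(seq_len(nrow(data)), data[[condition]])
  }
  purrr::map_dfr(names(groups), function(g) {
    idx <- groups[[g]]
    v <- vals_all[idx]
    fn <- stats::fivenum(v)
    tibble::tibble(
      condition = g,
      n_values = length(v),
      n_cells = if (!is.null(cell)) length(unique(data[[cell]][idx]))
                else NA_integer_,
      median = fn[3], q1 = fn[2], q3 = fn[4])
  })
}

new_comparison <- function(test_name, statistic, p_value, df = NULL,
                           pairwise = NULL, group_medians = NULL) {
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         df = df, pairwise = pairwise, group_medians = group_medians),
    class = "pol_comparison")
}

#' @export
print.pol_comparison <- function(x, ...) {
  cat(sprintf("<pol_comparison> %s: statistic %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat(sprintf("  Tukey HSD: %d pairs, %d with adjusted p < 0.05\n",
                nrow(x$pairwise), sum(x$pairwise$p_adj < 0.05)))
  }
  invisible(x)
}

#' Two-condition comparison (Student's t-test)
#'
#' Two-sided two-sample t-test on pooled per-punctum values, equal-variance
#' ("Student's") by default with Welch available by flag. Two samples with
#' zero variance and equal means return statistic 0 and p = 1 by convention.
#'
#' @param a,b Numeric vectors of per-punctum values (each length >= 2).
#' @param var_equal Assume equal variances (classical Student's test).
#' @return A `pol_comparison` object (see [tidy.pol_comparison()]).
#' @export
compare_two <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_comparison("Student's t-test", 0, 1,
                            df = length(a) + length(b) - 2,
                            group_medians = c(stats::median(a),
                                              stats::median(b))))
    }
    stop("both samples are constant with different means; the t statistic is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  new_comparison(
    if (var_equal) "Student's t-test" else "Welch's t-test",
    unname(tt$statistic), tt$p.value, df = unname(tt$parameter),
    group_medians = c(stats::median(a), stats::median(b)))
}

#' Multi-condition comparison (one-way ANOVA with Tukey post hoc)
#'
#' One-way ANOVA on pooled per-punctum values across three or more
#' conditions, with Tukey HSD adjusted pairwise comparisons.
#'
#' @param values Numeric vector of per-punctum values.
#' @param groups Factor/character vector of condition labels (>= 3 levels,
#'   each with >= 2 values).
#' @param posthoc Compute the Tukey HSD table (default `TRUE`).
#' @return A `pol_comparison` object with a `pairwise` tibble
#'   (`pair`, `difference`, `p_adj`) when `posthoc` is `TRUE`.
#' @export
compare_many <- function(values, groups, posthoc = TRUE) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  if (nlevels(groups) < 3) {
    stop("fewer than 3 groups: use compare_two()", call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    return(new_comparison(
      "one-way ANOVA", 0, 1,
      pairwise = if (posthoc) {
        lv <- levels(groups)
        pairs <- utils::combn(lv, 2)
        tibble::tibble(
          pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
          difference = 0, p_adj = 1)
      } else NULL))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  res <- new_comparison("one-way ANOVA", tab[["F value"]][1],
                        tab[["Pr(>F)"]][1],
                        df = tab[["Df"]])
  if (posthoc) {
    tk <- stats::TukeyHSD(fit)$groups
    res$pairwise <- tibble::tibble(
      pair = rownames(tk),
      difference = tk[, "diff"],
      p_adj = tk[, "p adj"])
  }
  res
}

#' Compare conditions in a punctum table
#'
#' Tidy front end to [compare_two()] / [compare_many()]: dispatches on the
#' number of condition levels present.
#'
#' @param data Data frame with one row per punctum.
#' @param value Value column name (default `ps_ratio`).
#' @param condition Condition column name (default `condition`).
#' @param ... Passed to [compare_two()] or [compare_many()].
#' @return A `pol_comparison` object.
#' @export
compare_conditions <- function(data, value = "ps_ratio",
                               condition = "condition", ...) {
  stopifnot(value %in% names(data), condition %in% names(data))
  g <- factor(data[[condition]])
  if (nlevels(g) < 2) stop("need at least 2 conditions", call. = FALSE)
  if (nlevels(g) == 2) {
    sp <- split(data[[value]], g)
    compare_two(sp[[1]], sp[[2]], ...)
  } else {
    compare_many(data[[value]], g, ...)
  }
}

#' Spatial-uniformity check of per-punctum values
#'
#' Ordinary least squares of the value on x and (separately) on y position,
#' in pixel units. A "uniform" verdict is returned when neither slope is
#' significant at `alpha`, mirroring the observation that p:s ratios do not
#' vary with position on the basal nuclear surface.
#'
#' @param data Data frame with value and position columns.
#' @param value,x,y Column names.
#' @param alpha Significance level for the verdict.
#' @return Object of class `spatial_trend`: tibble of per-axis `slope`,
#'   `p_value` plus a `uniform` flag.
#' @export
spatial_trend <- function(data, value = "ps_ratio", x = "x_px", y = "y_px",
                          alpha = 0.05) {
  stopifnot(all(c(value, x, y) %in% names(data)))
  v <- data[[value]]
  if (stats::var(data[[x]]) == 0 || stats::var(data[[y]]) == 0) {
    stop("positions are constant; no spatial trend is estimable",
         call. = FALSE)
  }
  one_axis <- function(pos, axis) {
    fit <- stats::lm(v ~ pos)
    cf <- summary(fit)$coefficients
    tibble::tibble(axis = axis, slope = cf[2, 1], p_value = cf[2, 4])
  }
  tab <- dplyr::bind_rows(one_axis(data[[x]], "x"), one_axis(data[[y]], "y"))
  structure(list(trends = tab, uniform = all(tab$p_value > alpha),
                 alpha = alpha),
            class = "spatial_trend")
}

#' @export
print.spatial_trend <- function(x, ...) {
  cat(sprintf("<spatial_trend> verdict: %s (alpha = %g)\n",
              if (x$uniform) "uniform" else "non-uniform", x$alpha))
  print(x$trends)
  invisible(x)
}

#' Unimodality check of punctum total intensities
#'
#' Counts the modes of a Gaussian kernel-density estimate at the Silverman
#' bandwidth scaled by each of `bw_factors`. The verdict is "single peak"
#' only if exactly one mode persists at every bandwidth; a single intensity
#' peak indicates that detected puncta are individual complexes rather than
#' a mixture of single and multiple complexes.
#'
#' @param total_intensities Numeric vector (>= 50 values for a verdict;
#'   fewer returns verdict "insufficient data" with a warning).
#' @param bw_factors Multipliers of the Silverman bandwidth.
#' @return List: `n_modes` (at the base bandwidth), `modes_by_bandwidth`,
#'   `verdict` (`"single peak"`, `"multiple peaks"` or
#'   `"insufficient data"`).
#' @export
unimodality_check <- function(total_intensities, bw_factors = c(1, 1.5, 2)) {
  x <- total_intensities[is.finite(total_intensities)]
  if (length(x) < 50) {
    warning("fewer than 50 values; unimodality verdict is unreliable",
            call. = FALSE)
    return(list(n_modes = NA_integer_,
                modes_by_bandwidth = rep(NA_integer_, length(bw_factors)),
                verdict = "insufficient data"))
  }
  if (stats::var(x) == 0) {
    return(list(n_modes = 1L, modes_by_bandwidth = rep(1L, length(bw_factors)),
                verdict = "single peak"))
  }
  count_modes <- function(bw) {
    d <- stats::density(x, bw = bw, n = 512)
    y <- d$y
    sum(diff(sign(diff(y))) == -2)
  }
  bw0 <- stats::bw.nrd0(x)
  modes <- vapply(bw_factors * bw0, count_modes, integer(1))
  # under Gaussian KDE smoothing modes only merge as bandwidth grows, so a
  # mode persists across the sweep iff it survives the coarsest bandwidth
  persistent <- min(modes)
  list(n_modes = persistent, modes_by_bandwidth = modes,
       verdict = if (persistent == 1L) "single peak" else "multiple peaks")
}
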