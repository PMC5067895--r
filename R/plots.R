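# ggplot2 views of the result tables. Each plot_* function accepts the tibble
# produced by the corresponding computation, so plots compose with the pipe.

#' Plot quality-score evolution across versions
#'
#' One line per metric, quality score (1-5) against version.
#'
#' @param scores Long score table (`version`, `metric`, `score`) from
#'   [score_table()].
#' @return A ggplot object.
#' @export
plot_score_evolution <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$version, y = .data$score,
                                       colour = .data$metric,
                                       group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(1, 5), breaks = 1:5) +
    ggplot2::labs(x = "version", y = "quality score", colour = "metric") +
    ggplot2::theme_minimal()
}

#' Plot the accumulative mean-change profile
#'
#' @param profile Tibble from [accumulative_profile()] (optionally with a
#'   `version` column, used for the x axis when present).
#' @return A ggplot object.
#' @export
plot_accumulative_profile <- function(profile) {
  xvar <- if ("version" %in% names(profile)) "version" else "step"
  ggplot2::ggplot(profile, ggplot2::aes(x = .data[[xvar]],
                                        y = .data$cumulative, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$imputed)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = xvar, y = "accumulative mean change") +
    ggplot2::theme_minimal()
}

#' Plot per-version frequency distributions of change levels
#'
#' @param stats Tibble from [corpus_change_statistics()] is not sufficient
#'   here; pass a long tibble with columns `version`, `level`, `count`, e.g.
#'   built with [frequency_distribution()] per pair.
#' @return A ggplot object (facets per version).
#' @export
plot_frequency_distributions <- function(stats) {
  stopifnot(all(c("version", "level", "count") %in% names(stats)))
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$count, y = factor(.data$level))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~version) +
    ggplot2::labs(x = "frequency", y = "change level") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.oquare_pca <- function(object, ...) {
  df <- tibble::as_tibble(object$loadings, rownames = "variable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor1, y = .data$factor2,
                                   label = .data$variable)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0), colour = "grey60") +
    ggplot2::geom_text(size = 3) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(
      x = sprintf("factor 1 (%.0f%%)", 100 * object$explained[[1]]),
      y = sprintf("factor 2 (%.0f%%)", 100 * object$explained[[2]])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
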