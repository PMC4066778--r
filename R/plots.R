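#' MA-style plot of a differential-binding fit
#'
#' Average abundance against log2 fold change, highlighting features whose
#' BH-adjusted P-value falls at or below `fdr`.
#'
#' @param object A `db_test` object.
#' @param fdr Highlight threshold.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.db_test <- function(object, fdr = 0.05, ...) {
  d <- object$table
  d$significant <- bh_adjust(d$pvalue) <= fdr
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$ave_log_cpm, y = .data$logFC,
    colour = .data$significant
  )) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(
      x = "average log2 CPM", y = "log2 fold change",
      colour = sprintf("FDR <= %.2g", fdr)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the fitted dispersion trend
#'
#' Per-feature trended NB dispersion against average abundance.
#'
#' @param trend A `dispersion_trend` object (or a `db_test`, whose trend is
#'   used).
#' @return A ggplot.
#' @export
plot_dispersion_trend <- function(trend) {
  if (inherits(trend, "db_test")) trend <- trend$trend
  stopifnot(inherits(trend, "dispersion_trend"))
  d <- dplyr::arrange(trend$table, .data$ave_log_cpm)
  ggplot2::ggplot(d, ggplot2::aes(.data$ave_log_cpm, .data$dispersion)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "average log2 CPM", y = "trended NB dispersion") +
    ggplot2::theme_minimal()
}

#' Plot an experiment report
#'
#' Bar chart of the per-condition means with +/- one standard error, laid
#' out by the report's grouping columns (strategies and thresholds for the
#' type I study; mode, spacing, method and metric for the FDR study; mode,
#' method and metric for the performance study).
#'
#' @param object An `experiment_report` from [run_type1()], [run_fdr()] or
#'   [run_performance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_report <- function(object, ...) {
  kind <- attr(object, "experiment")
  d <- tibble::as_tibble(object)
  if (identical(kind, "type1")) {
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$strategy, y = .data$mean
    )) +
      ggplot2::facet_wrap(ggplot2::vars(.data$threshold), scales = "free_y") +
      ggplot2::geom_hline(
        ggplot2::aes(yintercept = .data$threshold),
        linetype = "dotted"
      ) +
      ggplot2::labs(x = "strategy", y = "observed type I error rate")
  } else if (identical(kind, "fdr")) {
    d$x <- factor(d$spacing)
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$x, y = .data$mean, fill = .data$method
    )) +
      ggplot2::facet_grid(
        ggplot2::vars(.data$metric), ggplot2::vars(.data$mode)
      ) +
      ggplot2::geom_hline(yintercept = 0.05, linetype = "dotted") +
      ggplot2::labs(x = "window spacing (bp)", y = "observed FDR")
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$method, y = .data$mean
    )) +
      ggplot2::facet_grid(
        ggplot2::vars(.data$metric), ggplot2::vars(.data$mode),
        scales = "free_y"
      ) +
      ggplot2::labs(x = "method", y = "mean over iterations")
  }
  p +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.3
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
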