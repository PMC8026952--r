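#' Plot the bootstrap distribution of the shrinkage factor
#'
#' Histogram of the bootstrap shrinkage values with the mean (solid) and
#' 2.5/97.5 percentile bounds (dashed) marked.
#'
#' @param object A `boot_shrinkage`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boot_shrinkage
#' @export
autoplot.boot_shrinkage <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$s_mean, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "bootstrap shrinkage factor S", y = "count",
                  title = sprintf("mean S = %.2f [%.2f, %.2f]",
                                  object$s_mean, object$ci_low,
                                  object$ci_high))
}

#' Plot variability of a metric across methods and sample sizes
#'
#' Boxplots of one validation metric (or the tuning value) per method,
#' faceted by development sample size — the display used to compare the
#' stability of model-development methods.
#'
#' @param object A `scenario_results` tibble (possibly several scenarios
#'   bound together).
#' @param metric Column to display: `"cal_slope"`, `"citl"`, `"c_index"`,
#'   `"nagelkerke_r2"` or `"tuning"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scenario_results
#' @export
autoplot.scenario_results <- function(object, metric = "cal_slope", ...) {
  stopifnot(metric %in% c("cal_slope", "citl", "c_index", "nagelkerke_r2",
                          "tuning"))
  df <- dplyr::filter(tibble::as_tibble(object),
                      is.finite(.data[[metric]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                        y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~n_dev, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (metric == "cal_slope") {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed")
  }
  if (metric == "citl") {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  }
  p
}

#' Plot a subsampling shrinkage curve
#'
#' Mean bootstrap shrinkage factor with its 95% percentile interval as the
#' development sample shrinks.
#'
#' @param object A `shrinkage_curve` from [subsampling_shrinkage_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shrinkage_curve
#' @export
autoplot.shrinkage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$s_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "development sample size",
                  y = "uniform shrinkage factor S (mean, 95% CI)")
}

#' Plot per-individual prediction differences across a shrinkage interval
#'
#' @param object A `pred_diff` from [prediction_difference()].
#' @param ... Unused.
#' @return A ggplot histogram of absolute differences with the threshold
#'   marked.
#' @method autoplot pred_diff
#' @export
autoplot.pred_diff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$abs_diff)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "absolute difference in prediction", y = "count")
}
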