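#' Plot the posterior effect map of a fit
#'
#' Heat map of posterior-median coefficients over markers x transcripts,
#' with called associations outlined.
#'
#' @param object an `eqtl_fit`.
#' @param call_threshold robust-SD multiplier for [call_associations()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eqtl_fit <- function(object, call_threshold = 2.5, ...) {
  tab <- association_table(object, call_threshold = call_threshold)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = factor(.data$transcript_id, levels = object$transcript_ids),
    y = factor(.data$marker_id, levels = rev(object$marker_ids)),
    fill = .data$beta_median)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(tab, .data$called),
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "transcript", y = "marker",
                  fill = "posterior\nmedian effect",
                  title = sprintf("%s model: posterior effect map",
                                  object$model)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a simulation benchmark
#'
#' MCC (or another metric) against sample size, one line per model, in
#' the style of simulation power curves.
#'
#' @param bench tibble from [benchmark_models()].
#' @param metric column to plot (default `"mcc"`).
#' @return a ggplot object.
#' @export
plot_benchmark <- function(bench, metric = "mcc") {
  stopifnot(metric %in% names(bench))
  summ <- dplyr::summarise(
    dplyr::group_by(bench, .data$model, .data$n),
    mean = mean(.data[[metric]], na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$n, .data$mean,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = bench,
                        ggplot2::aes(.data$n, .data[[metric]],
                                     colour = .data$model),
                        alpha = 0.4, size = 1) +
    ggplot2::labs(x = "sample size N", y = metric,
                  title = "Simulation benchmark") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation concordance per repeat
#'
#' @param cv an `eqtl_cv`, or a list of them to compare models.
#' @return a ggplot object.
#' @export
plot_cv <- function(cv) {
  if (inherits(cv, "eqtl_cv")) cv <- list(cv)
  tab <- dplyr::bind_rows(lapply(cv, tidy))
  ggplot2::ggplot(tab, ggplot2::aes(.data$model, .data$ccc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "concordance correlation (CCC)",
                  title = "Monte Carlo cross-validation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
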