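# ggplot2 autoplot methods for the main result types.

#' @export
autoplot.tachometric_curve <- function(object, fit = NULL, ...) {
  df <- dplyr::filter(object, !.data$empty)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center_ms,
                                        y = .data$prop_correct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Raw processing time (ms)",
                  y = "Proportion correct") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(df$bin_center_ms), max(df$bin_center_ms), by = 1)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(bin_center_ms = xs,
                            prop_correct = eval_sigmoid(fit, xs)),
      color = "firebrick", linewidth = 0.7)
  }
  p
}

#' @export
autoplot.sigmoid_fit <- function(object, rpt_range = c(0, 400), ...) {
  xs <- seq(rpt_range[1], rpt_range[2], by = 1)
  ggplot2::ggplot(tibble::tibble(x = xs, v = eval_sigmoid(object, xs)),
                  ggplot2::aes(x = .data$x, y = .data$v)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Raw processing time (ms)",
                  y = "Fraction correct") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.neurometric_curve <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$s_roc))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rpt_ms, y = .data$s_roc))
  if ("ci68_low" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci68_low,
                                               ymax = .data$ci68_high),
                                  fill = "steelblue", alpha = 0.3)
  }
  p +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Raw processing time (ms)",
                  y = expression(S[ROC])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bias_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rpt_ms, y = .data$bias_hz)) +
    ggplot2::geom_line(color = "darkorange3") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Raw processing time (ms)",
                  y = "Presaccadic bias (spikes/s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.direction_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dir_deg, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "Saccade direction relative to target (deg)",
                  y = "Density (per deg)") +
    ggplot2::theme_minimal()
}
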