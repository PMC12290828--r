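# ggplot2 figures for the result types.

#' Plot a decoding time course
#'
#' Empirical metric per window with the chance level; if a first-level
#' shuffled matrix is supplied, its 5th--95th percentile band is drawn
#' underneath.
#'
#' @param object A `decoding_timecourse`.
#' @param shuffled Optional permutation x window matrix from
#'   [shuffled_decode()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoding_timecourse
#' @export
autoplot.decoding_timecourse <- function(object, shuffled = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_time_ms,
                                        y = .data$estimate))
  if (!is.null(shuffled)) {
    band <- tibble(
      window_time_ms = object$window_times,
      lo = apply(shuffled, 2, quantile, 0.05),
      hi = apply(shuffled, 2, quantile, 0.95)
    )
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$window_time_ms, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, fill = "grey80"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Time (ms)", y = toupper(object$metric),
                  title = sprintf("%d-class decoding (chance %.3g)",
                                  object$n_classes, object$chance)) +
    ggplot2::theme_minimal()
}

#' Plot per-window test results
#'
#' @param object A `stat_result`.
#' @param ... Unused.
#' @return A ggplot object showing raw and FDR-adjusted p-values with the
#'   alpha threshold; significant windows are marked.
#' @method autoplot stat_result
#' @export
autoplot.stat_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "window_time_ms", "p_raw", "p_fdr"),
    c("p_raw", "p_fdr"), names_to = "kind", values_to = "p"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_time_ms, y = .data$p,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(as_tibble(object), .data$significant),
      ggplot2::aes(x = .data$window_time_ms, y = .data$p_fdr),
      inherit.aes = FALSE, colour = "red"
    ) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (ms)", y = "p-value",
                  title = attr(object, "test")) +
    ggplot2::theme_minimal()
}

#' Plot a POD permutation test
#'
#' Null distribution of the second-level group-mean normalized POD with the
#' observed value.
#'
#' @param object A `pod_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pod_result
#' @export
autoplot.pod_result <- function(object, ...) {
  ggplot2::ggplot(tibble(pod = object$null_sample), ggplot2::aes(.data$pod)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "Group mean normalized POD", y = "Null draws",
                  title = sprintf("POD test: observed %.3f, p = %.3g",
                                  object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot condition-average ERP traces
#'
#' @param object An `erp_result`.
#' @param ... Unused.
#' @return A ggplot object of the posterior-average trace per condition.
#' @method autoplot erp_result
#' @export
autoplot.erp_result <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$time_ms, y = .data$posterior_mean_uv,
                               colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV)",
                  title = "Posterior-average ERP") +
    ggplot2::theme_minimal()
}
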