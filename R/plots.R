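#' Plot an ensemble trajectory
#'
#' One panel per state component, one line per unit.
#'
#' @param object an `ensemble_traj`.
#' @param component optional component index to restrict to.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_traj <- function(object, component = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(component)) df <- dplyr::filter(df, .data$component %in% !!component)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   group = .data$oscillator)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1L, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time", y = "state",
                  title = sprintf("%s ensemble (sigma = %g)",
                                  object$model_name, object$sigma))
}

#' Plot a power spectrum
#'
#' Log-power versus frequency with the detected dominant frequency marked.
#'
#' @param object a `spectrum_est`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum_est <- function(object, ...) {
  f0 <- dominant_frequency(object)
  p <- ggplot2::ggplot(object$table,
                       ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (cycles / time unit)", y = "power")
  if (!is.na(f0)) {
    p <- p + ggplot2::geom_vline(xintercept = f0, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Plot the synchronization-error series
#'
#' Pairwise squared-distance quantity over time, with the post-transient
#' window shaded and its ergodic average marked.
#'
#' @param object a `sync_stats`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sync_stats <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(.data$time, .data$pairwise_sq)) +
    ggplot2::annotate("rect", xmin = object$window[1L],
                      xmax = object$window[2L], ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$sync_error,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time", y = "pairwise squared distance")
}

#' Bound-sweep comparison plot
#'
#' Empirical synchronization error against the theoretical bound over a
#' coupling-strength grid (one line per network size), on log-log axes.
#'
#' @param sweep tibble as produced by the `fig3a_bound_sweep` experiment
#'   (columns `n`, `k`, `empirical_avg_to_com`, `bound_avg_to_com`).
#' @return a ggplot.
#' @export
plot_bound_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep, dplyr::all_of(c("empirical_avg_to_com", "bound_avg_to_com")),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value,
                                     colour = factor(.data$n),
                                     linetype = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "coupling strength k",
                  y = "mean squared distance to the population mean",
                  colour = "N", linetype = NULL)
}
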