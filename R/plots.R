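#' Plot an accuracy curve
#'
#' Accuracy versus window length with the 90% threshold and the resulting
#' optimal response time marked.
#'
#' @param object An [accuracy_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  tb <- t_best(object)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$window, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = tb, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "window length (s)", y = "recognition accuracy",
                  title = "Recognition accuracy vs. window length",
                  subtitle = sprintf("T_best = %.2f s", tb)) +
    ggplot2::theme_minimal()
}

#' Plot a scorecard
#'
#' Bars of the five index scores against their caps, annotated with the
#' total and the difficulty level.
#'
#' @param object A [total_and_level()] scorecard.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scorecard
#' @export
autoplot.scorecard <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$cap), fill = "grey85") +
    ggplot2::geom_col(ggplot2::aes(y = .data$points), fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "points",
                  title = sprintf("Total %.1f / 100, difficulty level %s",
                                  object$total, object$level)) +
    ggplot2::theme_minimal()
}

#' Plot an amplitude spectrum
#'
#' @param object An [amplitude_spectrum()] tibble.
#' @param fmax Upper frequency limit for the x axis, Hz. Default 60.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssvep_spectrum
#' @export
autoplot.ssvep_spectrum <- function(object, fmax = 60, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$freq <= fmax)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot cohort accuracies per algorithm
#'
#' @param results A [cohort_accuracy()] tibble.
#' @return A ggplot object with one point per subject and the cohort mean.
#' @export
plot_cohort_accuracy <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$algorithm, y = .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "pooled accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
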