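## ggplot2 autoplot() methods for the main result types.

#' Plot a heterogeneity summary
#'
#' Mean, quadratic mean and SNR of the per-participant coefficients as a
#' function of lag, one panel per statistic.
#'
#' @param object A `heterogeneity_summary` from [summarize_population()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot heterogeneity_summary
#' @export
autoplot.heterogeneity_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("mu", "qmean", "snr"),
                              names_to = "statistic", values_to = "value")
  long$statistic <- factor(long$statistic, c("mu", "qmean", "snr"),
                           c("mean", "quadratic mean", "SNR"))
  ggplot2::ggplot(long, ggplot2::aes(.data$lag, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "lag k", y = NULL,
                  title = "Population summaries of lagged coefficients")
}

#' Plot a calibration curve
#'
#' Empirical frequency of Heads against the mean predicted probability per
#' quantile bin, with the identity diagonal.
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  r <- attr(object, "r")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$predicted, .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(x = "predicted Pr(Heads)", y = "empirical Pr(Heads)",
                  title = sprintf("Calibration (R = %.3f)", r))
}

#' Plot a stationarity scan
#'
#' Prediction-error curves over the discount timescale, one line per
#' participant, with the selected timescales marked.
#'
#' @param object A `stationarity_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stationarity_scan
#' @export
autoplot.stationarity_scan <- function(object, ...) {
  cv <- object$curve[!is.na(object$curve$error) & object$curve$eta > 0, ]
  cv$timescale <- effective_timescale(cv$eta)
  ggplot2::ggplot(cv, ggplot2::aes(.data$timescale, .data$error,
                                   group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$best$timescale,
                        linetype = 3, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "timescale 1 / (1 - eta)  [trials]",
                  y = "one-step prediction error",
                  title = "Discounted-weight stationarity scan")
}

#' Plot per-participant prediction errors
#'
#' @param object A `predictor_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot predictor_result
#' @export
autoplot.predictor_result <- function(object, ...) {
  ggplot2::ggplot(object$by_participant, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(bins = 15, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = c(0.5, object$error_rate),
                        linetype = c(2, 1), colour = c("grey50", "firebrick")) +
    ggplot2::labs(x = "prediction error", y = "participants",
                  title = sprintf("%s (%s, L = %d): error %.3f",
                                  object$model, object$regime, object$L,
                                  object$error_rate))
}
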