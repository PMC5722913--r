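#' Plot a stationarity-robustness report
#'
#' One line per correction lag: the per-reading Spearman correlation
#' between stationarity-assuming and lag-corrected promoter activities.
#'
#' @param object a `stationarity_report` from [stationarity_robustness()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stationarity_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$rho,
                                       colour = factor(.data$lag))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reading", y = "Spearman ρ across promoters",
                  colour = "lag (readings)") +
    ggplot2::coord_cartesian(ylim = c(NA, 1)) +
    ggplot2::theme_minimal()
}

#' Plot clearance-fit R-squared profiles
#'
#' The mean R-squared across operon genes as a function of the candidate
#' speed, one panel-free line per operon, with the fitted optimum marked.
#'
#' @param object a `clearance_fit` from [clearance_lag_fit()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.clearance_fit <- function(object, ...) {
  prof <- dplyr::filter(object$profiles, is.finite(.data$r2))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$speed, y = .data$r2,
                                     group = .data$operon)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(data = object$fits,
                        ggplot2::aes(x = .data$best_speed, y = .data$best_r2),
                        inherit.aes = FALSE, colour = "red", size = 1) +
    ggplot2::labs(x = "candidate speed (nt/s)",
                  y = expression(mean ~ R^2 ~ across ~ genes)) +
    ggplot2::theme_minimal()
}

#' Histogram of the per-gene transcription speeds
#'
#' @param speed_table a (typically filtered) speed table.
#' @param binwidth histogram bin width in nt/s (default 2).
#' @return A ggplot object.
#' @export
plot_speed_distribution <- function(speed_table, binwidth = 2) {
  tb <- speed_table
  if ("passes_filter" %in% names(tb)) tb <- dplyr::filter(tb, .data$passes_filter)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "transcription speed (nt/s)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Agreement plot for two speed sets with the zero-intercept fit
#'
#' @param x,y paired speeds in nt/s (e.g. model-derived vs.
#'   clearance-derived).
#' @param fit optional [zero_intercept_fit()] result; computed if absent.
#' @return A ggplot object.
#' @export
plot_speed_agreement <- function(x, y, fit = NULL) {
  fit <- fit %||% zero_intercept_fit(x, y)
  tb <- tibble::tibble(x = x, y = y)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = fit$slope, intercept = 0, colour = "red") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "model-derived speed (nt/s)",
                  y = "comparison speed (nt/s)",
                  subtitle = sprintf("zero-intercept slope %.2f (95%% CI %.2f-%.2f)",
                                     fit$slope, fit$conf_low, fit$conf_high)) +
    ggplot2::theme_minimal()
}
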