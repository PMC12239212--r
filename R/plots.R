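#' Plot a simulated trajectory
#'
#' Genotype counts over time on a log10 axis (counts shifted by 1 so
#' extinct genotypes remain drawable).
#'
#' @param object A `rescue_trajectory`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rescue_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("s", "a", "m"),
                              names_to = "genotype", values_to = "cells")
  long$genotype <- factor(long$genotype, levels = c("s", "a", "m"),
                          labels = c("sensitive", "aneuploid", "mutant"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$cells + 1,
                                     color = .data$genotype)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "cells + 1",
                  title = paste("outcome:", attr(object, "outcome"))) +
    ggplot2::theme_minimal()
}

#' Plot a rescue-probability curve experiment
#'
#' Simulated rescue fractions with binomial error bars against the exact
#' and approximate theory curves; dashed verticals mark the threshold
#' sizes.
#'
#' @param object A `rescue_curve` from [rescue_curve_experiment()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rescue_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n, .data$p_sim)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_exact), color = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_approx), color = "grey50",
                       linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             color = "red", size = 0.3) +
    ggplot2::geom_vline(xintercept = attr(object, "n_star_aneuploid"),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "n_star_direct"),
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initial tumor size N (cells)",
                  y = "rescue probability") +
    ggplot2::theme_minimal()
}

#' Plot a survival curve
#'
#' @param object A `rescue_survival` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rescue_survival <- function(object, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "survival probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (all(c("ci_lo", "ci_hi") %in% names(object))) {
    g <- g + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                               ymax = .data$ci_hi),
                                  alpha = 0.2)
  }
  g
}

#' Plot window-of-opportunity curves
#'
#' @param object A `window_curves` tibble from
#'   [window_of_opportunity_experiment()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.window_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$survival,
                                       color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)",
                  y = "P(no successful mutant by t)") +
    ggplot2::theme_minimal()
}
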