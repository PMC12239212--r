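#' Tidy a parameter table
#'
#' Long `term`/`value` form of a `rescue_params` row, one row per field,
#' with units.
#'
#' @param x A `rescue_params` tibble (first row is used).
#' @param ... Ignored.
#' @return A tibble with columns `term`, `value`, `units`.
#' @export
tidy.rescue_params <- function(x, ...) {
  p <- x[1, ]
  units <- c(lambda_s = "1/day", mu_s = "1/day", lambda_a = "1/day",
             mu_a = "1/day", lambda_m = "1/day", mu_m = "1/day",
             u = "1/division", u_pre = "1/division", v = "1/division",
             v_a = "1/division", c = "1/day", n_init = "cells",
             carrying_capacity = "cells")
  tibble::tibble(term = names(units),
                 value = as.numeric(p[1, names(units)]),
                 units = unname(units))
}

#' One-row summary of a parameter set
#'
#' Derived rates, regime classification and (when the theory applies)
#' threshold sizes for a single parameter row.
#'
#' @param x A `rescue_params` tibble (first row is used).
#' @param ... Ignored.
#' @return A one-row tibble.
#' @export
glance.rescue_params <- function(x, ...) {
  p <- x[1, ]
  d <- derived_rates(p)
  reg <- classify_regime(p)
  out <- dplyr::bind_cols(d, tibble::tibble(regime = reg$regime))
  th <- tryCatch(rescue_thresholds(p), error = function(e) NULL)
  if (!is.null(th)) {
    out <- dplyr::bind_cols(
      out, th[, c("n_star_direct", "n_star_aneuploid", "rescue_prob")])
  }
  out
}

#' Per-replicate records of an ensemble
#'
#' @param x A `rescue_ensemble`.
#' @param ... Ignored.
#' @return The replicate-level tibble (already tidy).
#' @export
tidy.rescue_ensemble <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a replicate ensemble
#'
#' Outcome counts, the rescue fraction with its binomial 95 percent
#' confidence interval, and mean rescue/recurrence/detection times over the
#' replicates where the event occurred.
#'
#' @param x A `rescue_ensemble`.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @export
glance.rescue_ensemble <- function(x, ...) {
  n <- nrow(x)
  k <- sum(x$outcome %in% c("rescued", "recurred"))
  p_hat <- k / n
  ci <- binomial_ci(p_hat, n)
  tibble::tibble(
    n_replicates = n,
    n_rescued = k,
    n_extinct = sum(x$outcome == "extinct"),
    n_censored = sum(x$outcome == "censored"),
    p_rescue = p_hat,
    ci_lo = ci[, "lo"], ci_hi = ci[, "hi"],
    mean_rescue_time = mean(x$rescue_time, na.rm = TRUE),
    mean_recurrence_time = mean(x$recurrence_time, na.rm = TRUE),
    mean_detection_time = mean(x$detection_time, na.rm = TRUE)
  )
}
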