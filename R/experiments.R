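#' Percentile bootstrap confidence interval
#'
#' Resamples `samples` with replacement `b` times, applies the statistic to
#' each resample, and returns the empirical 2.5th and 97.5th percentiles
#' (or the corresponding tail quantiles for another `conf`). Constant input
#' yields a degenerate zero-width interval.
#'
#' @param samples Numeric vector (length >= 2). For
#'   `statistic = "proportion"` the values should be 0/1 indicators.
#' @param statistic `"mean"`, `"median"` or `"proportion"`.
#' @param b Number of bootstrap resamples (>= 100).
#' @param seed Optional seed.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' bootstrap_ci(rbinom(200, 1, 0.5), statistic = "proportion", seed = 1)
#' @export
bootstrap_ci <- function(samples, statistic = c("mean", "median", "proportion"),
                         b = 1000, seed = NULL, conf = 0.95) {
  statistic <- match.arg(statistic)
  n <- length(samples)
  stopifnot(n >= 2, b >= 100)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(samples[sample.int(n, n * b, replace = TRUE)], nrow = n)
  stat <- switch(statistic,
                 mean = colMeans(draws),
                 proportion = colMeans(draws),
                 median = apply(draws, 2, stats::median))
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE)
  c(low = q[1], high = q[2])
}

binomial_ci <- function(p_hat, n) {
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  cbind(lo = pmax(0, p_hat - half), hi = pmin(1, p_hat + half))
}

#' Rescue probability versus initial tumor size
#'
#' For each tumor size in `n_grid`, runs a replicate ensemble and records
#' the simulated rescue fraction with its binomial 95 percent confidence
#' interval alongside the exact (`1 - q_s^N`) and approximate
#' (`1 - exp(-N/N*)`) theory curves. The threshold sizes `Nm*` and `Na*`
#' are attached as attributes for plotting as vertical references.
#'
#' Intended for desk-scaled parameters (mutation rate raised, sizes
#' lowered) so each point runs in seconds; the analytic curves are valid at
#' any scale.
#'
#' @param params A one-row `rescue_params` tibble (scaled).
#' @param n_grid Initial tumor sizes to sweep.
#' @param replicates Replicates per size.
#' @param base_seed Integer seed; mandatory.
#' @param method Simulation method, see [run_replicates()].
#' @return A tibble of class `rescue_curve` with columns `n`, `rescued`,
#'   `p_sim`, `ci_lo`, `ci_hi`, `p_exact`, `p_approx`, `replicates`.
#' @export
rescue_curve_experiment <- function(params, n_grid, replicates = 100,
                                    base_seed, method = "ssa") {
  stopifnot(length(n_grid) >= 1, replicates >= 1)
  rows <- purrr::map(seq_along(n_grid), function(i) {
    p <- params
    p$n_init <- n_grid[i]
    ens <- run_replicates(p, replicates, base_seed = derive_seed(base_seed, i),
                          method = method)
    k <- sum(ens$outcome == "rescued")
    tibble::tibble(n = n_grid[i], rescued = k, p_sim = k / replicates)
  })
  out <- dplyr::bind_rows(rows)
  ci <- binomial_ci(out$p_sim, replicates)
  out$ci_lo <- ci[, "lo"]; out$ci_hi <- ci[, "hi"]
  out$p_exact <- rescue_probability(params, out$n, method = "exact")
  out$p_approx <- rescue_probability(params, out$n, method = "approx")
  out$replicates <- replicates
  class(out) <- c("rescue_curve", class(out))
  attr(out, "params") <- params
  attr(out, "n_star_direct") <- threshold_direct(params)
  attr(out, "n_star_aneuploid") <- as.numeric(threshold_aneuploid(params))
  out
}

# Bisection estimate (in log size) of the tumor size at which the simulated
# rescue frequency crosses 1 - 1/e ~ 0.632, the defining property of the
# threshold size N* = 1/p_s.
simulated_threshold <- function(params, replicates, base_seed,
                                n_lo = NULL, n_hi = NULL, iterations = 7) {
  p_s <- extinction_probabilities(params)$p_s
  guess <- 1 / p_s
  if (is.null(n_lo)) n_lo <- guess / 16
  if (is.null(n_hi)) n_hi <- guess * 16
  freq_at <- function(n, seed) {
    p <- params
    p$n_init <- max(1, round(n))
    ens <- run_replicates(p, replicates, base_seed = seed)
    mean(ens$outcome == "rescued")
  }
  for (it in seq_len(iterations)) {
    mid <- sqrt(n_lo * n_hi)
    f <- freq_at(mid, derive_seed(base_seed, it))
    if (f < 1 - exp(-1)) n_lo <- mid else n_hi <- mid
  }
  sqrt(n_lo * n_hi)
}

#' Threshold size versus aneuploid growth rate
#'
#' Sweeps the aneuploid division rate and reports, per value: the
#' branch-formula threshold `Na*` with its branch, the exact threshold
#' `1/p_s` from the extinction probabilities, and (when `replicates > 0`) a
#' simulated threshold located by bisection on the tumor size at which the
#' rescue frequency crosses `1 - 1/e`. The direct-mutation threshold `Nm*`
#' is attached as a horizontal reference.
#'
#' @param params A one-row `rescue_params` tibble (scaled when simulating).
#' @param lambda_a_grid Aneuploid division rates to sweep.
#' @param replicates Replicates per bisection evaluation (0 = theory only).
#' @param base_seed Integer seed (required when `replicates > 0`).
#' @return A tibble of class `threshold_sweep` with columns `lambda_a`,
#'   `r_a`, `branch`, `n_star_branch`, `n_star_exact`, and `n_star_sim`
#'   when simulated.
#' @export
threshold_vs_ra_experiment <- function(params, lambda_a_grid, replicates = 0,
                                       base_seed = NULL) {
  if (replicates > 0 && is.null(base_seed)) {
    rlang::abort("base_seed is required when replicates > 0")
  }
  rows <- purrr::map(seq_along(lambda_a_grid), function(i) {
    p <- params
    p$lambda_a <- lambda_a_grid[i]
    na <- threshold_aneuploid(p)
    exact <- 1 / extinction_probabilities(p)$p_s
    row <- tibble::tibble(
      lambda_a = p$lambda_a, r_a = p$lambda_a - p$mu_a,
      branch = attr(na, "branch"), n_star_branch = as.numeric(na),
      n_star_exact = exact
    )
    if (replicates > 0) {
      row$n_star_sim <- simulated_threshold(p, replicates,
                                            derive_seed(base_seed, 100 + i))
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("threshold_sweep", class(out))
  attr(out, "n_star_direct") <- threshold_direct(params)
  attr(out, "params") <- params
  out
}

#' Standing versus de novo variation experiment
#'
#' Evaluates how rescue from pre-existing (standing) aneuploid cells
#' compares with rescue from drug-induced (de novo) aneuploidy, sweeping
#' either the sensitive death rate (`vary = "mu_s"`, which moves `r_s`) or
#' the pretreatment missegregation rate (`vary = "u_pre"`). Reports the
#' threshold ratios (standing/de novo and standing/direct) per grid value;
#' with `replicates > 0` it also runs scaled ensembles initialized with and
#' without the standing aneuploid fraction `f = u_pre lambda_s / c` and
#' records both rescue frequencies.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param vary `"mu_s"` or `"u_pre"`.
#' @param grid Values for the varied field.
#' @param replicates Replicates per point (0 = theory only).
#' @param base_seed Integer seed (required when `replicates > 0`).
#' @return A tibble of class `standing_sweep`.
#' @export
standing_variation_experiment <- function(params, vary = c("mu_s", "u_pre"),
                                          grid, replicates = 0,
                                          base_seed = NULL) {
  vary <- match.arg(vary)
  if (replicates > 0 && is.null(base_seed)) {
    rlang::abort("base_seed is required when replicates > 0")
  }
  rows <- purrr::map(seq_along(grid), function(i) {
    p <- params
    p[[vary]] <- grid[i]
    ratios <- threshold_ratios(p)
    row <- tibble::tibble(
      value = grid[i], vary = vary,
      r_s = p$lambda_s - p$mu_s,
      u_pre_over_u = p$u_pre / p$u,
      ratio_standing_aneuploid = ratios$ratio_standing_aneuploid,
      ratio_standing_direct = ratios$ratio_standing_direct
    )
    if (replicates > 0) {
      ens_sv <- run_replicates(p, replicates,
                               base_seed = derive_seed(base_seed, 2 * i),
                               standing_variation = "stochastic")
      ens_dn <- run_replicates(p, replicates,
                               base_seed = derive_seed(base_seed, 2 * i + 1))
      row$p_rescue_standing <- mean(ens_sv$outcome == "rescued")
      row$p_rescue_denovo <- mean(ens_dn$outcome == "rescued")
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("standing_sweep", class(out))
  attr(out, "params") <- params
  out
}

#' Window-of-opportunity experiment
#'
#' Overlays, for a set of aneuploidy conditions, the probability that no
#' successful resistant lineage has appeared by time `t`. Conditions where
#' the hazard construction applies (no aneuploidy, tolerant aneuploids) get
#' analytic curves; stationary and resistant conditions fall back to
#' Monte-Carlo over SSA ensembles when `replicates > 0` and are omitted
#' otherwise. Aneuploidy extends the window of opportunity: at late times
#' (`t > 1/|r_s|`, when the sensitive population is gone) only the `u > 0`
#' curves keep declining.
#'
#' @param params A one-row `rescue_params` tibble; its `u` is used for the
#'   aneuploid conditions.
#' @param n Initial tumor size.
#' @param t_grid Times, days.
#' @param lambda_a_values Named vector of aneuploid division rates defining
#'   the conditions.
#' @param include_none Include the `u = 0` (no aneuploidy) condition.
#' @param replicates Monte-Carlo ensemble size for non-analytic conditions.
#' @param base_seed Integer seed (required when `replicates > 0`).
#' @param conditioned Condition the curves on rescue occurring.
#' @return A tibble of class `window_curves` with columns `condition`, `t`,
#'   `survival`, `source` (+ CI columns for Monte-Carlo rows).
#' @export
window_of_opportunity_experiment <- function(params, n, t_grid,
                                             lambda_a_values = NULL,
                                             include_none = TRUE,
                                             replicates = 0, base_seed = NULL,
                                             conditioned = FALSE) {
  if (is.null(lambda_a_values)) {
    lambda_a_values <- c(tolerant = params$lambda_a)
  }
  conds <- list()
  if (include_none) {
    p0 <- params; p0$u <- 0
    conds$none <- p0
  }
  for (nm in names(lambda_a_values)) {
    p1 <- params; p1$lambda_a <- lambda_a_values[[nm]]
    conds[[nm]] <- p1
  }
  rows <- purrr::imap(conds, function(p, nm) {
    analytic_ok <- p$u == 0 || (p$lambda_a - p$mu_a) < 0
    if (analytic_ok) {
      s <- rescue_time_survival(p, n, t_grid, conditioned = conditioned)
      tibble::tibble(condition = nm, t = s$t, survival = s$survival,
                     source = "analytic")
    } else if (replicates > 0) {
      if (is.null(base_seed)) {
        rlang::abort("base_seed is required when replicates > 0")
      }
      s <- rescue_time_survival(p, n, t_grid, conditioned = conditioned,
                                method = "monte_carlo",
                                replicates = replicates,
                                base_seed = derive_seed(base_seed,
                                                        which(names(conds) == nm)))
      tibble::tibble(condition = nm, t = s$t, survival = s$survival,
                     ci_lo = s$ci_lo, ci_hi = s$ci_hi, source = "monte_carlo")
    } else {
      NULL
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("window_curves", class(out))
  attr(out, "n") <- n
  out
}

#' Recurrence time versus tumor size
#'
#' For each initial size: the small-tumor asymptote
#' `-1/r_s - 1/r_a + ln(p_m N)/r_m`, the Monte-Carlo
#' inhomogeneous-Poisson estimate with its standard error, and the
#' large-tumor constant `(1/r_m) ln((r_m - r_s)/(v lambda_s))`. With
#' `replicates > 0` a scaled SSA estimate (mean recurrence time among
#' replicates that recurred) is added; that path is only feasible for
#' desk-scaled parameters.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n_grid Initial tumor sizes.
#' @param n_draws Monte-Carlo draws per size.
#' @param base_seed Integer seed.
#' @param replicates SSA replicates per size (0 = none).
#' @return A tibble of class `recurrence_sweep` with columns `n`,
#'   `tau_small_n`, `tau_mc`, `se_mc`, `tau_large_n` (+ `tau_ssa`,
#'   `n_recurred` when simulated).
#' @export
recurrence_experiment <- function(params, n_grid, n_draws = 2000, base_seed,
                                  replicates = 0) {
  d <- derived_rates(params)
  tau_large <- log((d$r_m - d$r_s) / (params$v * params$lambda_s)) / d$r_m
  rows <- purrr::map(seq_along(n_grid), function(i) {
    n <- n_grid[i]
    small <- (if (params$u == 0) -1 / d$r_s else -1 / d$r_s - 1 / d$r_a) +
      log(d$p_m * n) / d$r_m
    mc <- mean_recurrence_time(params, n, method = "monte_carlo",
                               n_draws = n_draws,
                               seed = derive_seed(base_seed, i))
    row <- tibble::tibble(n = n, tau_small_n = small,
                          tau_mc = as.numeric(mc), se_mc = attr(mc, "se"),
                          tau_large_n = tau_large)
    if (replicates > 0) {
      p <- params
      p$n_init <- n
      ens <- run_replicates(
        p, replicates, base_seed = derive_seed(base_seed, 1000 + i),
        stop = stop_rule(recurrence_target = n))
      rec <- ens$recurrence_time[ens$outcome == "recurred"]
      row$tau_ssa <- if (length(rec) > 0) mean(rec) else NA_real_
      row$n_recurred <- length(rec)
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recurrence_sweep", class(out))
  attr(out, "params") <- params
  out
}
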