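# (exp(r1*t) - exp(r2*t)) / (r1 - r2), stable as r1 -> r2
exp_diff <- function(r1, r2, t) {
  d <- r1 - r2
  if (abs(d) < 1e-12) {
    t * exp(r1 * t) * (1 + d * t / 2)
  } else {
    (exp(r1 * t) - exp(r2 * t)) / d
  }
}

# (exp(r*t) - 1) / r, stable as r -> 0
expm1_over <- function(r, t) {
  if (abs(r) < 1e-14) t else expm1(r * t) / r
}

#' Mean-field (deterministic) trajectories
#'
#' Expected genotype counts of the branching process, which coincide with
#' the solution of the mean-field ODE system: `s(t) = N exp(r_s t)`;
#' `a(t) = u lambda_s N (exp(r_s t) - exp(r_a t)) / (r_s - r_a)` (with the
#' `t exp(r_s t)` limit when the rates coincide); and `m(t)` solving
#' `dm/dt = v lambda_s s + v_a lambda_a a + r_m m` by closed-form
#' integration. Valid as a description of the stochastic model's ensemble
#' mean at all sizes, and of a single trajectory only while counts are
#' large.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial number of sensitive cells.
#' @param t_grid Nonnegative times (days).
#' @return A tibble with columns `t`, `s_bar`, `a_bar`, `m_bar`.
#' @examples
#' deterministic_trajectory(rescue_preset("melanoma_a375"), 1e7,
#'                          t_grid = c(0, 50, 100))
#' @export
deterministic_trajectory <- function(params, n, t_grid) {
  stopifnot(nrow(params) == 1, all(t_grid >= 0))
  d <- derived_rates(params)
  rs <- d$r_s; ra <- d$r_a; rm <- d$r_m
  p <- params
  s_bar <- n * exp(rs * t_grid)
  a_bar <- vapply(t_grid, function(t) {
    if (p$u == 0) 0 else p$u * p$lambda_s * n * exp_diff(rs, ra, t)
  }, numeric(1))
  m_bar <- vapply(t_grid, function(t) {
    direct <- p$v * p$lambda_s * n * exp_diff(rs, rm, t)
    via_a <- if (p$u == 0 || p$v_a == 0) 0 else {
      dd <- rs - ra
      if (abs(dd) < 1e-12) {
        # a(t) = u*lambda_s*N*t*exp(rs t); integrate t e^{rs tau} against
        # e^{rm (t - tau)}: d/d rs of exp_diff(rs, rm, t)
        e <- rs - rm
        p$v_a * p$lambda_a * p$u * p$lambda_s * n *
          exp(rm * t) * (t * exp(e * t) / e - expm1(e * t) / e^2)
      } else {
        p$v_a * p$lambda_a * p$u * p$lambda_s * n / dd *
          (exp_diff(rs, rm, t) - exp_diff(ra, rm, t))
      }
    }
    direct + via_a
  }, numeric(1))
  tibble::tibble(t = t_grid, s_bar = s_bar, a_bar = a_bar, m_bar = m_bar)
}

#' Cumulative hazard of evolutionary rescue
#'
#' Models the arrival of successful resistant lineages (lineages that
#' escape drift, probability `p_m` each) as an inhomogeneous Poisson process
#' whose intensity follows the deterministic sensitive and aneuploid
#' populations:
#' `Lambda(t) = p_m * integral_0^t (v lambda_s s(tau) +
#' v_a lambda_a a(tau)) dtau`, evaluated in closed form. The total hazard
#' satisfies `Lambda(Inf) = N/Nm* + N/Na*` (tolerant branch) exactly, and
#' `1 - exp(-Lambda(Inf))` is the approximate rescue probability.
#'
#' The construction treats the aneuploid dynamics deterministically, so it
#' is only exposed where lineage-level stochasticity is subdominant: both
#' `r_s < 0` and either `u = 0` or `r_a < 0` (direct-mutation and tolerant
#' regimes). Stationary and resistant regimes must use simulation.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size, cells.
#' @return An object of class `rescue_hazard`: a list with elements
#'   `Lambda` (vectorized function of time), `Lambda_inf`, `Lambda_direct`,
#'   `Lambda_aneuploid`, `params`, `n`.
#' @examples
#' h <- rescue_hazard(rescue_preset("melanoma_a375"), 1e7)
#' h$Lambda_inf
#' @export
rescue_hazard <- function(params, n) {
  stopifnot(nrow(params) == 1, n >= 0)
  d <- derived_rates(params)
  rs <- d$r_s; ra <- d$r_a; pm <- d$p_m
  p <- params
  if (rs >= 0) rlang::abort("rescue hazard requires declining sensitive cells (r_s < 0)")
  if (p$u > 0 && ra >= 0) {
    rlang::abort(paste0(
      "unsupported regime: the hazard construction needs r_a < 0 (or u = 0); ",
      "use Monte-Carlo simulation for stationary/resistant aneuploids"))
  }
  lam_direct <- pm * p$v * p$lambda_s * n
  lam_via_a <- if (p$u == 0) 0 else pm * p$v_a * p$lambda_a * p$u * p$lambda_s * n
  Lambda <- function(t) {
    vapply(t, function(tt) {
      Is <- expm1_over(rs, tt)                      # integral of e^{rs tau}
      Ia <- if (lam_via_a == 0) 0 else {
        (expm1_over(rs, tt) - expm1_over(ra, tt)) / (rs - ra)
      }
      lam_direct * Is + lam_via_a * Ia
    }, numeric(1))
  }
  L_dir <- lam_direct / abs(rs)
  L_an <- if (lam_via_a == 0) 0 else lam_via_a / (abs(rs) * abs(ra))
  structure(list(Lambda = Lambda, Lambda_inf = L_dir + L_an,
                 Lambda_direct = L_dir, Lambda_aneuploid = L_an,
                 params = params, n = n),
            class = "rescue_hazard")
}

# Shared asymptotic-branch selection for time quantities. Branches switch at
# N <= Na_eff/10 (small) and N >= 10*Nm* (large); Na_eff is the aneuploid
# threshold in the tolerant regime and the direct threshold when u = 0.
time_branch <- function(params, n) {
  regime <- as.character(classify_regime(params)$regime)
  if (!regime %in% c("direct_mutation", "tolerant")) {
    rlang::abort(paste0(
      "unsupported regime '", regime, "' for the analytic time layer; ",
      "use stochastic simulation (run_replicates) instead"))
  }
  nm <- threshold_direct(params)
  na_eff <- if (regime == "direct_mutation") nm
            else as.numeric(threshold_aneuploid(params))
  small_cut <- min(na_eff, nm) / 10
  if (n <= small_cut) "asymptotic_small_N"
  else if (n >= 10 * nm) "asymptotic_large_N"
  else "intermediate"
}

#' Mean evolutionary rescue time
#'
#' Expected waiting time, conditioned on rescue occurring, for the
#' appearance of the resistant lineage that escapes extinction. For small
#' tumors (`N` at most a tenth of the governing threshold) this is
#' `-1/r_s - 1/r_a` (just `-1/r_s` when `u = 0`): a rapidly declining
#' population that is nevertheless rescued must have been rescued early.
#' For large tumors (`N >= 10 Nm*`) mutations arrive essentially at a
#' constant rate and the mean is `(1 / (v lambda_s N)) * (lambda_m / r_m)`.
#' In between, the mean is computed by integrating the conditional survival
#' function of the rescue-hazard construction,
#' `integral (exp(-Lambda(t)) - exp(-Lambda(Inf))) / (1 - exp(-Lambda(Inf))) dt`.
#'
#' Only available in the direct-mutation and tolerant regimes (see
#' [rescue_hazard()]).
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size, cells.
#' @return Mean rescue time in days, with the evaluation branch in
#'   attribute `"method"`.
#' @examples
#' mean_rescue_time(rescue_preset("melanoma_a375"), 1e5)  # ~1e4 days
#' @export
mean_rescue_time <- function(params, n) {
  d <- derived_rates(params)
  branch <- time_branch(params, n)
  val <- switch(branch,
    asymptotic_small_N = if (params$u == 0) -1 / d$r_s
                         else -1 / d$r_s - 1 / d$r_a,
    asymptotic_large_N = (1 / (params$v * params$lambda_s * n)) *
                         (params$lambda_m / d$r_m),
    intermediate = {
      h <- rescue_hazard(params, n)
      Li <- h$Lambda_inf
      denom <- -expm1(-Li)
      f <- function(t) (exp(-h$Lambda(t)) - exp(-Li)) / denom
      stats::integrate(f, 0, Inf, rel.tol = 1e-8,
                       subdivisions = 1000L)$value
    })
  if (branch == "intermediate") branch <- "hazard_integral"
  structure(val, method = branch)
}

#' Survival function of the rescue time
#'
#' Probability that no successful resistant lineage has appeared by time
#' `t`. The analytic path uses the rescue hazard: `exp(-Lambda(t))`
#' unconditioned, or
#' `(exp(-Lambda(t)) - exp(-Lambda(Inf))) / (1 - exp(-Lambda(Inf)))`
#' conditioned on rescue eventually happening. The Monte-Carlo path (any
#' regime, intended for desk-scaled parameters) runs an SSA ensemble and
#' reports the empirical survival of the recorded rescue times with a
#' binomial 95 percent confidence band.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size, cells (overrides `params$n_init` for the
#'   Monte-Carlo path as well).
#' @param t_grid Times, days.
#' @param conditioned Condition on rescue occurring.
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param replicates,base_seed Ensemble size and seed for the Monte-Carlo
#'   path.
#' @return A tibble of class `rescue_survival` with columns `t`,
#'   `survival`, and for Monte-Carlo also `ci_lo`, `ci_hi`.
#' @export
rescue_time_survival <- function(params, n, t_grid, conditioned = FALSE,
                                 method = c("analytic", "monte_carlo"),
                                 replicates = 200, base_seed = NULL) {
  method <- match.arg(method)
  if (method == "analytic") {
    h <- rescue_hazard(params, n)
    surv <- exp(-h$Lambda(t_grid))
    if (conditioned) {
      Li <- h$Lambda_inf
      surv <- (surv - exp(-Li)) / (1 - exp(-Li))
    }
    out <- tibble::tibble(t = t_grid, survival = surv)
  } else {
    if (is.null(base_seed)) {
      rlang::abort("base_seed is required for the Monte-Carlo path")
    }
    p <- params
    p$n_init <- n
    ens <- run_replicates(p, replicates, base_seed = base_seed)
    times <- ens$rescue_time
    rescued <- !is.na(times)
    surv <- vapply(t_grid, function(tt) {
      if (conditioned) {
        if (!any(rescued)) NA_real_ else mean(times[rescued] > tt)
      } else {
        mean(!rescued | times > tt)
      }
    }, numeric(1))
    nn <- if (conditioned) sum(rescued) else length(times)
    half <- 1.96 * sqrt(surv * (1 - surv) / max(nn, 1))
    out <- tibble::tibble(t = t_grid, survival = surv,
                          ci_lo = pmax(0, surv - half),
                          ci_hi = pmin(1, surv + half))
  }
  class(out) <- c("rescue_survival", class(out))
  attr(out, "conditioned") <- conditioned
  attr(out, "method") <- method
  out
}

# Draw conditioned rescue-lineage arrival ensembles: number of successful
# lineages ~ Poisson(Lambda_inf) truncated to >= 1, arrival times iid with
# density dLambda/dt / Lambda_inf (inverted numerically on a time grid).
# Returns a list of sorted arrival-time vectors.
sample_rescue_arrivals <- function(params, n, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- rescue_hazard(params, n)
  d <- derived_rates(params)
  slow <- if (params$u > 0) max(d$r_s, d$r_a) else d$r_s  # least-negative rate
  t_max <- 40 / abs(slow)
  # refine near zero where the direct-path intensity decays on 1/|r_s|
  grid <- sort(unique(c(seq(0, min(t_max, 40 / abs(d$r_s)), length.out = 2048),
                        seq(0, t_max, length.out = 4096))))
  Lg <- h$Lambda(grid)
  Li <- h$Lambda_inf
  p0 <- exp(-Li)
  k <- stats::qpois(p0 + stats::runif(n_draws) * (1 - p0), Li)
  k[k < 1] <- 1L
  lapply(k, function(ki) {
    u <- stats::runif(ki) * Li
    u <- pmin(u, Lg[length(Lg)])  # clip draws beyond the resolved tail
    sort(stats::approx(Lg, grid, xout = u, ties = "ordered")$y)
  })
}

# First time the summed sizes of conditioned lineages reach `target`.
# Lineage born at t_i grows deterministically as (1/p_m) exp(r_m (t - t_i)).
crossing_time_from_arrivals <- function(arrivals, p_m, r_m, target) {
  # log-sum-exp of the lineage weights exp(-r_m t_i): t_i can be large
  # enough that the weights underflow, so work on the log scale throughout
  x <- -r_m * arrivals               # arrivals sorted ascending, x descending
  lcw <- x[1] + log(cumsum(exp(x - x[1])))
  k <- length(arrivals)
  for (j in seq_len(k)) {
    cand <- (log(target * p_m) - lcw[j]) / r_m
    cand <- max(cand, arrivals[j])   # a lineage cannot count before birth
    if (j == k || cand <= arrivals[j + 1]) return(cand)
  }
  cand
}

#' Mean recurrence time
#'
#' Expected time, conditioned on rescue, for the resistant population to
#' climb back to `target` cells (by convention the pretreatment size `N`).
#' Small tumors: `-1/r_s - 1/r_a + ln(p_m N) / r_m` -- the mean rescue time
#' plus the growth time of a single conditioned lineage, which grows like
#' `(1/p_m) exp(r_m t)`. Large tumors (`N >= 10 Nm*`, `target = N`): mutant
#' dynamics are deterministic and the mean approaches the N-independent
#' constant `(1 / r_m) ln((r_m - r_s) / (v lambda_s))`. Intermediate sizes
#' use Monte-Carlo over the inhomogeneous-Poisson rescue-lineage arrivals:
#' successful lineages arrive with hazard `dLambda`, each contributes
#' `(1/p_m) exp(r_m (t - t_i))` cells, and recurrence is the first time the
#' contributions sum to `target`.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size, cells.
#' @param target Mutant count defining recurrence (default `n`).
#' @param method `"auto"` picks the branch by tumor size;
#'   `"monte_carlo"` forces the lineage Monte-Carlo.
#' @param n_draws Conditioned Monte-Carlo draws (>= 2000 recommended).
#' @param seed Seed for the Monte-Carlo path.
#' @return Mean recurrence time in days; attribute `"method"` records the
#'   branch and, for Monte-Carlo, attribute `"se"` its standard error.
#' @examples
#' mean_recurrence_time(rescue_preset("melanoma_a375"), 1e10)  # ~1540 days
#' @export
mean_recurrence_time <- function(params, n, target = n,
                                 method = c("auto", "monte_carlo"),
                                 n_draws = 2000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(target >= 1)
  d <- derived_rates(params)
  branch <- if (method == "monte_carlo") "monte_carlo" else time_branch(params, n)
  if (branch == "asymptotic_large_N" && target != n) branch <- "ode"
  val <- switch(branch,
    asymptotic_small_N = {
      base <- if (params$u == 0) -1 / d$r_s else -1 / d$r_s - 1 / d$r_a
      base + log(d$p_m * target) / d$r_m
    },
    asymptotic_large_N = log((d$r_m - d$r_s) /
                             (params$v * params$lambda_s)) / d$r_m,
    ode = ode_crossing_time(params, n, target),
    {
      arr <- sample_rescue_arrivals(params, n, n_draws, seed = seed)
      tt <- vapply(arr, crossing_time_from_arrivals,
                   numeric(1), p_m = d$p_m, r_m = d$r_m, target = target)
      out <- mean(tt)
      attr(out, "se") <- stats::sd(tt) / sqrt(length(tt))
      attr(out, "sample") <- tt
      out
    })
  if (branch == "intermediate") branch <- "monte_carlo"
  attr(val, "method") <- branch
  val
}

# Deterministic crossing time of the mean-field mutant trajectory
ode_crossing_time <- function(params, n, target) {
  f <- function(t) {
    deterministic_trajectory(params, n, t)$m_bar - target
  }
  upper <- 10
  while (f(upper) < 0 && upper < 1e7) upper <- upper * 2
  stats::uniroot(f, c(1e-8, upper), tol = 1e-8)$root
}

#' Mean detection time
#'
#' Expected time, conditioned on rescue, for the resistant population to
#' reach a clinical detection threshold of `detection_target` cells. Uses
#' the same machinery as [mean_recurrence_time()] with the detection
#' threshold as target, except that for large tumors (where mutant dynamics
#' are deterministic) the crossing time of the mean-field trajectory is
#' used, so detection at `M < N` comes earlier than recurrence.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size, cells.
#' @param detection_target Detection threshold M, cells.
#' @param ... Passed to [mean_recurrence_time()].
#' @return Mean detection time in days with attribute `"method"`.
#' @export
mean_detection_time <- function(params, n, detection_target, ...) {
  stopifnot(detection_target >= 1)
  mean_recurrence_time(params, n, target = detection_target, ...)
}

#' Survival function of the recurrence time
#'
#' Monte-Carlo estimate, over the conditioned rescue-lineage construction,
#' of the probability that the resistant population has not reached
#' `target` cells by each time in `t_grid`, with a binomial 95 percent
#' confidence band.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size, cells.
#' @param target Mutant count defining recurrence (default `n`).
#' @param t_grid Times, days.
#' @param n_draws Conditioned draws.
#' @param seed Seed.
#' @return A tibble of class `rescue_survival` with columns `t`,
#'   `survival`, `ci_lo`, `ci_hi`; the sampled recurrence times are in
#'   attribute `"sample"`.
#' @export
recurrence_survival <- function(params, n, target = n, t_grid,
                                n_draws = 2000, seed = NULL) {
  d <- derived_rates(params)
  arr <- sample_rescue_arrivals(params, n, n_draws, seed = seed)
  tt <- vapply(arr, crossing_time_from_arrivals,
               numeric(1), p_m = d$p_m, r_m = d$r_m, target = target)
  surv <- vapply(t_grid, function(x) mean(tt > x), numeric(1))
  half <- 1.96 * sqrt(surv * (1 - surv) / length(tt))
  out <- tibble::tibble(t = t_grid, survival = surv,
                        ci_lo = pmax(0, surv - half),
                        ci_hi = pmin(1, surv + half))
  class(out) <- c("rescue_survival", class(out))
  attr(out, "sample") <- tt
  attr(out, "method") <- "monte_carlo"
  out
}

#' Rescue, recurrence and detection time summary
#'
#' Convenience wrapper returning the three mean times with their evaluation
#' branches as a one-row tibble.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size, cells (default `params$n_init`).
#' @param target Recurrence target (default `n`).
#' @param detection_target Detection threshold M (default `1e7`).
#' @param n_draws,seed Monte-Carlo controls.
#' @return A one-row tibble with the means (days) and method tags.
#' @export
time_summaries <- function(params, n = params$n_init, target = n,
                           detection_target = 1e7, n_draws = 2000,
                           seed = NULL) {
  tr <- mean_rescue_time(params, n)
  trec <- mean_recurrence_time(params, n, target = target,
                               n_draws = n_draws, seed = seed)
  tdet <- mean_detection_time(params, n, detection_target,
                              n_draws = n_draws, seed = seed)
  tibble::tibble(
    mean_rescue_time = as.numeric(tr),
    rescue_method = attr(tr, "method"),
    mean_recurrence_time = as.numeric(trec),
    recurrence_method = attr(trec, "method"),
    mean_detection_time = as.numeric(tdet),
    detection_method = attr(tdet, "method")
  )
}
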