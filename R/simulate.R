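#' The nine-channel event table
#'
#' Returns the instantaneous rates of the nine events of the birth-death
#' model at a given state `(s, a, m)`: birth and death of each genotype,
#' missegregation of a dividing sensitive cell (adds an aneuploid daughter,
#' parent count unchanged), and mutation of a dividing sensitive or
#' aneuploid cell (adds a mutant daughter). By default division rates use
#' the approximation `lambda_s * s * (1 - u - v) ~ lambda_s * s` (and
#' likewise `(1 - v_a)` for aneuploids), valid because `u, v << 1`; set
#' `exact_division_factors = TRUE` to restore the exact factors for
#' sensitivity checks. If the parameter row carries a finite
#' `carrying_capacity` K, each genotype's death rate gains the logistic
#' crowding term `lambda_k * (s + a + m) / K`.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param s,a,m Cell counts.
#' @param exact_division_factors Keep the `(1 - u - v)` and `(1 - v_a)`
#'   division factors.
#' @return A nine-row tibble: `event`, `rate` (1/day), and the state
#'   increments `d_s`, `d_a`, `d_m`.
#' @examples
#' event_rates(rescue_preset("melanoma_a375"), s = 1, a = 0, m = 0)
#' @export
event_rates <- function(params, s, a, m, exact_division_factors = FALSE) {
  stopifnot(nrow(params) == 1, s >= 0, a >= 0, m >= 0)
  p <- params
  K <- p$carrying_capacity
  crowd <- if (is.finite(K) && K > 0) (s + a + m) / K else 0
  fs <- if (exact_division_factors) 1 - p$u - p$v else 1
  fa <- if (exact_division_factors) 1 - p$v_a else 1
  tibble::tibble(
    event = c("sensitive_birth", "sensitive_death", "missegregation",
              "sensitive_mutation", "aneuploid_birth", "aneuploid_death",
              "aneuploid_mutation", "mutant_birth", "mutant_death"),
    rate = c(p$lambda_s * s * fs,
             (p$mu_s + p$lambda_s * crowd) * s,
             p$u * p$lambda_s * s,
             p$v * p$lambda_s * s,
             p$lambda_a * a * fa,
             (p$mu_a + p$lambda_a * crowd) * a,
             p$v_a * p$lambda_a * a,
             p$lambda_m * m,
             (p$mu_m + p$lambda_m * crowd) * m),
    d_s = c(1L, -1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    d_a = c(0L, 0L, 1L, 0L, 1L, -1L, 0L, 0L, 0L),
    d_m = c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, -1L)
  )
}

#' Mutant count at which establishment is virtually certain
#'
#' Smallest number of mutant cells whose joint probability of stochastic
#' extinction drops below 0.1 percent, obtained by solving
#' `1 - (1 - p_m)^m = 0.999` with `p_m = r_m / lambda_m`:
#' `floor(3 ln 10 / ln(lambda_m / mu_m)) + 1`. Simulations stop and declare
#' the tumor rescued once the mutant count reaches this threshold.
#'
#' @param params A one-row `rescue_params` tibble.
#' @return An integer count of mutant cells.
#' @examples
#' mutant_establishment_threshold(rescue_preset("melanoma_a375"))  # 66
#' @export
mutant_establishment_threshold <- function(params) {
  stopifnot(nrow(params) == 1)
  if (params$lambda_m <= params$mu_m) {
    stop("mutant cannot establish: requires lambda_m > mu_m")
  }
  if (params$mu_m == 0) return(1L)
  as.integer(floor(3 * log(10) / log(params$lambda_m / params$mu_m)) + 1)
}

#' Stopping rule for simulation runs
#'
#' At least one terminating condition must be active. `establishment = NULL`
#' auto-computes [mutant_establishment_threshold()]; use
#' `establishment = 0` to disable outcome classification (e.g. drug-free
#' runs bounded by `max_time`). Recurrence and detection targets are counts
#' of mutant cells; reaching the recurrence target classifies the run as
#' `recurred`.
#'
#' @param establishment Mutant count that ends the run as `rescued`
#'   (`NULL` = auto).
#' @param recurrence_target Optional mutant count for recurrence (the
#'   conventional choice is the initial tumor size `n_init`).
#' @param detection_target Optional mutant count for clinical detection.
#' @param max_time Censoring time, days.
#' @param max_events Censoring event count.
#' @return A list of class `stop_rule`.
#' @export
stop_rule <- function(establishment = NULL, recurrence_target = NULL,
                      detection_target = NULL, max_time = 1e6,
                      max_events = 1e9) {
  has_term <- is.null(establishment) || establishment > 0 ||
    !is.null(recurrence_target) || is.finite(max_time) || is.finite(max_events)
  if (!has_term) stop("stop rule has no terminating condition")
  structure(list(establishment = establishment,
                 recurrence_target = recurrence_target,
                 detection_target = detection_target,
                 max_time = max_time, max_events = max_events),
            class = "stop_rule")
}

#' Initial population state, optionally with standing variation
#'
#' Builds the starting state for a simulation. With `mode = "none"` all
#' `n_init` cells are sensitive. Before treatment, missegregation at rate
#' `u_pre` balanced by the fitness cost `c` keeps a fraction
#' `f = u_pre * lambda_s / c` of cells aneuploid; `mode = "expected"` seeds
#' `round(f * N)` aneuploid cells deterministically and
#' `mode = "stochastic"` draws the aneuploid count from Binomial(N, f).
#' Mutants are always absent initially.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param mode `"none"`, `"expected"` or `"stochastic"`.
#' @return A one-row tibble with columns `s`, `a`, `m`.
#' @examples
#' initial_state(rescue_preset("melanoma_a375"), mode = "expected")
#' @export
initial_state <- function(params, mode = c("none", "expected", "stochastic")) {
  mode <- match.arg(mode)
  stopifnot(nrow(params) == 1)
  n <- params$n_init
  if (mode == "none" || params$u_pre == 0) {
    return(tibble::tibble(s = n, a = 0, m = 0))
  }
  f <- derived_rates(params)$f_standing
  if (f >= 1) stop("standing aneuploid fraction f must be < 1")
  a0 <- if (mode == "expected") {
    round(f * n)
  } else if (n <= .Machine$integer.max) {
    stats::rbinom(1, size = as.integer(n), prob = f)
  } else {
    # normal approximation for counts beyond integer range
    max(0, round(stats::rnorm(1, mean = f * n, sd = sqrt(n * f * (1 - f)))))
  }
  tibble::tibble(s = n - a0, a = a0, m = 0)
}

outcome_levels <- c("extinct", "rescued", "recurred", "censored")

#' Simulate one tumor trajectory
#'
#' Runs the three-genotype birth-death model once, either with the exact
#' Gillespie stochastic simulation algorithm (`method = "ssa"`: exponential
#' waiting times with the summed event rate, event chosen proportionally to
#' its rate) or with tau-leaping (`method = "tau"`: fixed steps of
#' `tau_step` days, Poisson event counts per channel, genotype counts
#' clamped at zero). A finite `carrying_capacity` in `params` switches on
#' logistic density-dependent death rates in either method. Runs are
#' bit-reproducible from `seed`.
#'
#' In SSA runs every mutant-founding event opens a tracked lineage, and the
#' reported `rescue_time` is the birth time of the earliest lineage still
#' alive when the establishment threshold is crossed -- the waiting time for
#' the resistant lineage that avoids extinction. Tau-leap runs do not track
#' lineages and report the crossing time itself.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param seed Integer seed; mandatory, recorded in the result.
#' @param method `"ssa"` (default) or `"tau"`.
#' @param tau_step Tau-leap step, days.
#' @param stop A [stop_rule()].
#' @param init Optional one-row tibble `(s, a, m)` overriding the initial
#'   state; default is [initial_state()] with `standing_variation`.
#' @param standing_variation Passed to [initial_state()] when `init` is
#'   `NULL`.
#' @param record_interval Trajectory thinning interval in days; `NULL`
#'   records every event (SSA) or every leap (tau).
#' @param exact_division_factors See [event_rates()].
#' @return A tibble of class `rescue_trajectory` with columns `t`, `s`, `a`,
#'   `m` and attributes `outcome`, `rescue_time`, `establish_time`,
#'   `recurrence_time`, `detection_time`, `first_mutant_time`,
#'   `event_counts`, `n_events`, `final_state`, `seed`, `method`, `params`.
#' @examples
#' p <- rescue_preset("melanoma_a375", v = 1e-3, n_init = 500)
#' tr <- simulate_tumor(p, seed = 1)
#' attr(tr, "outcome")
#' @export
simulate_tumor <- function(params, seed, method = c("ssa", "tau"),
                           tau_step = 0.1, stop = stop_rule(), init = NULL,
                           standing_variation = "none",
                           record_interval = NULL,
                           exact_division_factors = FALSE) {
  method <- match.arg(method)
  stopifnot(nrow(params) == 1)
  validate_rescue_params(params, quiet = TRUE)
  if (missing(seed) || is.null(seed)) {
    rlang::abort("an explicit integer seed is required for every stochastic run")
  }
  set.seed(seed)
  if (is.null(init)) init <- initial_state(params, mode = standing_variation)
  est <- stop$establishment
  if (is.null(est)) est <- mutant_establishment_threshold(params)
  K <- params$carrying_capacity
  if (!is.finite(K)) K <- NA_real_
  rec <- if (is.null(stop$recurrence_target)) NA_real_ else stop$recurrence_target
  det <- if (is.null(stop$detection_target)) NA_real_ else stop$detection_target
  ri <- if (is.null(record_interval)) -1 else record_interval

  fn <- if (method == "ssa") ssa_run_cpp else tau_leap_run_cpp
  args <- list(params$lambda_s, params$mu_s, params$lambda_a, params$mu_a,
               params$lambda_m, params$mu_m, params$u, params$v, params$v_a,
               if (is.na(K)) Inf else K, exact_division_factors,
               init$s, init$a, init$m)
  if (method == "tau") args <- c(args, tau_step)
  args <- c(args, est, rec, det, stop$max_time, stop$max_events, ri)
  res <- do.call(fn, args)

  traj <- tibble::tibble(t = res$time, s = res$s, a = res$a, m = res$m)
  class(traj) <- c("rescue_trajectory", class(traj))
  attr(traj, "outcome") <- outcome_levels[res$outcome + 1]
  attr(traj, "rescue_time") <- res$rescue_time
  attr(traj, "establish_time") <- res$establish_time
  attr(traj, "recurrence_time") <- res$recurrence_time
  attr(traj, "detection_time") <- res$detection_time
  attr(traj, "first_mutant_time") <- res$first_mutant_time
  attr(traj, "event_counts") <- stats::setNames(
    res$event_counts, event_rates(params, 1, 1, 1)$event)
  attr(traj, "n_events") <- res$n_events
  attr(traj, "final_state") <- stats::setNames(res$final, c("s", "a", "m"))
  attr(traj, "seed") <- seed
  attr(traj, "method") <- method
  attr(traj, "params") <- params
  traj
}

# Stable counter-based replicate seed derivation (Weyl sequence on the
# 2^31 - 1 ring); recorded in outputs so ensembles are machine-portable.
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) %% 2147483647 +
                (as.numeric(i) * 2654435761) %% 2147483647) %% 2147483647)
}

#' Run a replicate ensemble
#'
#' Repeats [simulate_tumor()] `n_replicates` times with per-replicate seeds
#' derived deterministically from `(base_seed, replicate index)`, collecting
#' one outcome record per replicate. Censored replicates are reported as
#' such, never dropped.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Integer base seed; mandatory.
#' @param method `"ssa"`, `"tau"`, or `"logistic"` (SSA with the logistic
#'   death term; requires a finite `carrying_capacity` in `params`).
#' @param stop A [stop_rule()].
#' @param standing_variation Passed to [initial_state()].
#' @param tau_step Tau-leap step, days.
#' @param exact_division_factors See [event_rates()].
#' @param progress Print progress every `progress` replicates (0 = quiet).
#' @return A tibble of class `rescue_ensemble` with columns `replicate`,
#'   `seed`, `outcome`, `rescue_time`, `recurrence_time`, `detection_time`,
#'   `final_s`, `final_a`, `final_m`; attributes `params`, `method`,
#'   `base_seed`, `stop`, `establishment_threshold`.
#' @examples
#' p <- rescue_preset("melanoma_a375", v = 1e-3, n_init = 200)
#' ens <- run_replicates(p, n_replicates = 20, base_seed = 7)
#' table(ens$outcome)
#' @export
run_replicates <- function(params, n_replicates, base_seed,
                           method = c("ssa", "tau", "logistic"),
                           stop = stop_rule(), standing_variation = "none",
                           tau_step = 0.1, exact_division_factors = FALSE,
                           progress = 0) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1)
  if (missing(base_seed) || is.null(base_seed)) {
    rlang::abort("an explicit integer base_seed is required for every ensemble")
  }
  if (method == "logistic") {
    if (!is.finite(params$carrying_capacity)) {
      rlang::abort("method 'logistic' requires a finite carrying_capacity in params")
    }
    method <- "ssa"
  }
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    seed_i <- derive_seed(base_seed, i)
    tr <- simulate_tumor(params, seed = seed_i, method = method,
                         tau_step = tau_step, stop = stop,
                         standing_variation = standing_variation,
                         record_interval = Inf,
                         exact_division_factors = exact_division_factors)
    fin <- attr(tr, "final_state")
    rows[[i]] <- tibble::tibble(
      replicate = i, seed = seed_i, outcome = attr(tr, "outcome"),
      rescue_time = attr(tr, "rescue_time"),
      recurrence_time = attr(tr, "recurrence_time"),
      detection_time = attr(tr, "detection_time"),
      final_s = fin[["s"]], final_a = fin[["a"]], final_m = fin[["m"]]
    )
    if (progress > 0 && i %% progress == 0) {
      message("replicate ", i, "/", n_replicates, " done")
    }
  }
  ens <- dplyr::bind_rows(rows)
  ens$outcome <- factor(ens$outcome, levels = outcome_levels)
  class(ens) <- c("rescue_ensemble", class(ens))
  attr(ens, "params") <- params
  attr(ens, "method") <- method
  attr(ens, "base_seed") <- base_seed
  attr(ens, "stop") <- stop
  attr(ens, "establishment_threshold") <-
    if (is.null(stop$establishment)) mutant_establishment_threshold(params)
    else stop$establishment
  ens
}
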