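#' Lineage extinction probabilities from the branching process
#'
#' Treats each founding cell as the root of an independent multitype
#' branching process and computes the probability that its lineage goes
#' extinct without ever establishing a resistant mutant population.
#' `q_s`, `q_a`, `q_m` are the extinction probabilities of a lineage founded
#' by one sensitive, aneuploid or mutant cell; `p_s = 1 - q_s` is the rescue
#' probability per sensitive cell and `p_m = 1 - q_m` the establishment
#' probability of a single mutant lineage.
#'
#' The probabilities are the minimal fixed points of the offspring
#' probability-generating functions of the event table. They solve, in
#' order,
#' `q_m = min(1, mu_m / lambda_m)`, then the quadratic
#' `lambda_a (1 - v_a) q^2 - (lambda_a + mu_a - v_a lambda_a q_m) q + mu_a = 0`
#' (smaller root in `[0, 1]`), then
#' `lambda_s (1 - u - v) q^2 - (lambda_s + mu_s - u lambda_s q_a -
#' v lambda_s q_m) q + mu_s = 0`.
#' Roots are evaluated with a cancellation-safe quadratic formula. With
#' `method = "iterate"` the same fixed points are found instead by iterating
#' the PGF map from `q = 0`, which serves as an independent numerical route
#' to the identical quantity.
#'
#' @param params A `rescue_params` tibble.
#' @param method `"closed_form"` (default) or `"iterate"`.
#' @param tol Convergence tolerance for the iterative method.
#' @param max_iter Iteration cap for the iterative method.
#' @return A tibble with columns `q_s`, `q_a`, `q_m`, `p_s`, `p_m`.
#' @examples
#' extinction_probabilities(rescue_preset("melanoma_a375"))
#' @export
extinction_probabilities <- function(params, method = c("closed_form", "iterate"),
                                     tol = 1e-14, max_iter = 1e7) {
  method <- match.arg(method)
  validate_rescue_params(params, quiet = TRUE)
  n <- nrow(params)
  out <- tibble::tibble(q_s = numeric(n), q_a = numeric(n), q_m = numeric(n),
                        p_s = numeric(n), p_m = numeric(n))
  for (i in seq_len(n)) {
    p <- params[i, ]
    if (method == "closed_form") {
      q_m <- if (p$lambda_m == 0) 1 else min(1, p$mu_m / p$lambda_m)
      q_a <- pgf_quad_root(p$lambda_a * (1 - p$v_a),
                           p$lambda_a + p$mu_a - p$v_a * p$lambda_a * q_m,
                           p$mu_a)
      q_s <- pgf_quad_root(p$lambda_s * (1 - p$u - p$v),
                           p$lambda_s + p$mu_s - p$u * p$lambda_s * q_a -
                             p$v * p$lambda_s * q_m,
                           p$mu_s)
    } else {
      qq <- pgf_iterate(p, tol = tol, max_iter = max_iter)
      q_s <- qq[1]; q_a <- qq[2]; q_m <- qq[3]
    }
    out$q_s[i] <- q_s; out$q_a[i] <- q_a; out$q_m[i] <- q_m
    out$p_s[i] <- 1 - q_s; out$p_m[i] <- 1 - q_m
  }
  out
}

# Smaller root in [0, 1] of a*q^2 - b*q + c0 = 0 (b > 0), computed without
# catastrophic cancellation: the smaller root is 2*c0 / (b + sqrt(disc)).
# a -> 0 degenerates to the linear (pure-death) case q = c0 / b.
pgf_quad_root <- function(a, b, c0) {
  if (a <= .Machine$double.eps * b) {
    return(min(1, c0 / b))
  }
  disc <- b * b - 4 * a * c0
  if (disc < 0) disc <- 0  # guards roundoff at criticality
  q <- 2 * c0 / (b + sqrt(disc))
  min(1, q)
}

# Fixed-point iteration of the offspring PGF map from q = 0; independent
# numerical oracle for extinction_probabilities(). The type hierarchy is
# triangular (m feeds a feeds s), so the three fixed points are solved in
# sequence, each by Steffensen-accelerated iteration in extended precision
# (see src/pgf.cpp): plain iteration converges only linearly -- and
# arbitrarily slowly near criticality -- and the residual cancellation near
# a critical point exceeds double precision.
pgf_iterate <- function(p, tol = 1e-14, max_iter = 1e7) {
  q <- pgf_iterate_cpp(p$lambda_s, p$mu_s, p$lambda_a, p$mu_a,
                       p$lambda_m, p$mu_m, p$u, p$v, p$v_a,
                       tol, max_iter)
  c(q_s = q[1], q_a = q[2], q_m = q[3])
}

#' Probability of evolutionary rescue
#'
#' Probability that a tumor of `n` independent sensitive founder cells is
#' rescued (produces an established resistant population) rather than going
#' extinct under the drug. The exact form is `1 - q_s^n` with `q_s` from
#' [extinction_probabilities()]; the approximate form is
#' `1 - exp(-n / N*)` with the threshold size `N*` built from the
#' regime-appropriate branches (direct path only in the `direct_mutation`
#' regime; direct plus aneuploid path otherwise). `N* = 1 / p_s` is the
#' tumor size above which rescue becomes likely.
#'
#' @param params A one-row `rescue_params` tibble.
#' @param n Initial tumor size(s), cells; vectorized.
#' @param method `"exact"` or `"approx"`.
#' @return Rescue probability, same length as `n`.
#' @examples
#' p <- rescue_preset("melanoma_a375")
#' rescue_probability(p, c(1e6, 1e7, 1e8))
#' @export
rescue_probability <- function(params, n, method = c("exact", "approx")) {
  method <- match.arg(method)
  stopifnot(nrow(params) == 1, all(n >= 0))
  if (method == "exact") {
    q_s <- extinction_probabilities(params)$q_s
    if (q_s >= 1) return(rep(0, length(n)))
    # -expm1(n*log(q_s)) is 1 - q_s^n without underflow for q_s near 1
    return(-expm1(n * log(q_s)))
  }
  haz <- total_hazard_per_cell(params)
  -expm1(-n * haz)
}

# Per-founder-cell total rescue hazard n/N* used by the approximate rescue
# probability: 1/Nm* always, plus 1/Na* when aneuploidy is frequent enough.
total_hazard_per_cell <- function(params) {
  regime <- as.character(classify_regime(params)$regime)
  haz <- 1 / threshold_direct(params)
  if (regime != "direct_mutation") {
    haz <- haz + 1 / as.numeric(threshold_aneuploid(params))
  }
  as.numeric(haz)
}

#' Threshold tumor size for rescue by direct mutation
#'
#' The initial tumor size above which a direct resistance mutation in a
#' sensitive cell is likely to rescue the tumor:
#' `Nm* = (|r_s| / (v lambda_s)) * (lambda_m / r_m)`. The first factor is
#' the ratio of the sensitive population's decay rate to its mutation rate;
#' the second is the inverse establishment probability of a mutant lineage.
#' Aneuploidy parameters do not enter.
#'
#' @param params A `rescue_params` tibble.
#' @return Threshold size(s) in cells (`Inf` when `v = 0`).
#' @examples
#' threshold_direct(rescue_preset("melanoma_a375"))  # ~4e7 cells
#' @export
threshold_direct <- function(params) {
  d <- derived_rates(params)
  if (any(d$r_s >= 0)) {
    stop("threshold sizes require declining sensitive cells (r_s < 0)")
  }
  ifelse(params$v > 0,
         (abs(d$r_s) / (params$v * params$lambda_s)) * (params$lambda_m / d$r_m),
         Inf)
}

#' Threshold tumor size for rescue via aneuploidy
#'
#' The initial tumor size above which the two-step path (missegregation to
#' an aneuploid, then a resistance mutation on the aneuploid background, or
#' outright regrowth by resistant aneuploids) is likely to rescue the tumor.
#' All branches share the prefactor `|r_s| / (u lambda_s)`, multiplied by:
#' `(|r_a| / (v_a lambda_a)) * (lambda_m / r_m)` for tolerant aneuploids;
#' `2 lambda_a T* = sqrt(lambda_m / (v_a r_m))` for stationary aneuploids
#' (exact at `r_a = 0`); and `lambda_a / r_a` for resistant aneuploids. The
#' branch is chosen by [classify_regime()]; in the `direct_mutation` regime
#' the aneuploid path is negligible and [threshold_direct()] is returned
#' with branch `"direct"`.
#'
#' @param params A `rescue_params` tibble.
#' @return Threshold size(s) in cells, with the branch used attached as
#'   attribute `"branch"` (character vector).
#' @examples
#' threshold_aneuploid(rescue_preset("melanoma_a375"))  # ~4e6, tolerant
#' @export
threshold_aneuploid <- function(params) {
  d <- derived_rates(params)
  regime <- as.character(classify_regime(params)$regime)
  if (any(d$r_s >= 0)) {
    stop("threshold sizes require declining sensitive cells (r_s < 0)")
  }
  pre <- ifelse(params$u > 0, abs(d$r_s) / (params$u * params$lambda_s), Inf)
  factor <- numeric(nrow(params))
  branch <- character(nrow(params))
  for (i in seq_len(nrow(params))) {
    if (regime[i] == "direct_mutation") {
      branch[i] <- "direct"
      next
    }
    factor[i] <- switch(regime[i],
      tolerant   = (abs(d$r_a[i]) / (params$v_a[i] * params$lambda_a[i])) *
                   (params$lambda_m[i] / d$r_m[i]),
      stationary = 2 * params$lambda_a[i] * d$t_star[i],
      resistant  = params$lambda_a[i] / d$r_a[i]
    )
    branch[i] <- regime[i]
  }
  out <- ifelse(branch == "direct", threshold_direct(params), pre * factor)
  attr(out, "branch") <- branch
  out
}

#' Threshold-size ratios
#'
#' Ratios comparing the three rescue routes. `ratio_aneuploid_direct`
#' (Na*/Nm*) is the quotient of [threshold_aneuploid()] and
#' [threshold_direct()]; values below 1 mean aneuploidy lowers the tumor
#' size needed for likely rescue. `ratio_standing_aneuploid` (the
#' standing-variation threshold over the de novo one) is
#' `(u / u_pre) * (c / |r_s|)`: rescue from pre-existing aneuploid cells is
#' governed by the drug-free cost `c` where de novo rescue is governed by
#' the decline rate `|r_s|`, and by the pre-drug missegregation rate `u_pre`
#' instead of `u`. `ratio_standing_direct` is their product, so the three
#' ratios are mutually consistent by construction.
#'
#' @param params A `rescue_params` tibble.
#' @return A tibble with columns `ratio_aneuploid_direct`,
#'   `ratio_standing_aneuploid`, `ratio_standing_direct`, `branch`.
#' @examples
#' threshold_ratios(rescue_preset("melanoma_a375"))
#' @export
threshold_ratios <- function(params) {
  d <- derived_rates(params)
  na <- threshold_aneuploid(params)
  nm <- threshold_direct(params)
  r_ad <- as.numeric(na) / nm
  r_sa <- ifelse(params$u_pre > 0,
                 (params$u / params$u_pre) * (params$c / abs(d$r_s)),
                 Inf)
  tibble::tibble(
    ratio_aneuploid_direct = r_ad,
    ratio_standing_aneuploid = r_sa,
    ratio_standing_direct = r_sa * r_ad,
    branch = attr(na, "branch")
  )
}

#' Full threshold and rescue-probability summary
#'
#' One-stop theory table: threshold sizes for the direct
#' (`n_star_direct`), aneuploid (`n_star_aneuploid`) and standing-variation
#' (`n_star_standing`) routes, the three ratios, the regime branch used, and
#' the exact rescue probability at the parameter row's `n_init`.
#'
#' @param params A `rescue_params` tibble.
#' @return A tibble, one row per parameter row.
#' @examples
#' rescue_thresholds(rescue_preset("melanoma_a375"))
#' @export
rescue_thresholds <- function(params) {
  na <- threshold_aneuploid(params)
  nm <- threshold_direct(params)
  ratios <- threshold_ratios(params)
  prob <- vapply(seq_len(nrow(params)), function(i) {
    rescue_probability(params[i, ], params$n_init[i])
  }, numeric(1))
  tibble::tibble(
    n_star_direct = nm,
    n_star_aneuploid = as.numeric(na),
    n_star_standing = ratios$ratio_standing_aneuploid * as.numeric(na),
    ratio_aneuploid_direct = ratios$ratio_aneuploid_direct,
    ratio_standing_aneuploid = ratios$ratio_standing_aneuploid,
    ratio_standing_direct = ratios$ratio_standing_direct,
    branch = ratios$branch,
    rescue_prob = prob
  )
}
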