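test_that("extinction probabilities: limits and published values", {
  # no rescue path and subcritical growth: certain extinction
  q0 <- extinction_probabilities(melanoma(u = 0, v = 0))
  expect_equal(q0$q_s, 1)
  expect_equal(q0$p_s, 0)
  # mutant lineage: q_m = mu_m / lambda_m
  q <- extinction_probabilities(melanoma())
  expect_equal(q$q_m, 0.9)
  expect_equal(q$p_m, 0.1)
  # the exact threshold 1/p_s is close to the tolerant-branch approximation
  n_exact <- 1 / q$p_s
  n_approx <- 1 / (1 / threshold_direct(melanoma()) +
                     1 / as.numeric(threshold_aneuploid(melanoma())))
  expect_lt(max(n_exact / n_approx, n_approx / n_exact), 1.5)
})

test_that("closed-form roots agree with the fixed-point iteration oracle", {
  set.seed(42)
  for (i in 1:150) {
    p <- random_params()
    a <- extinction_probabilities(p, method = "closed_form")
    b <- extinction_probabilities(p, method = "iterate",
                                  tol = 1e-15, max_iter = 2e5)
    expect_lt(abs(a$q_s - b$q_s), 1e-10)
    expect_lt(abs(a$q_a - b$q_a), 1e-10)
    expect_lt(abs(a$q_m - b$q_m), 1e-10)
    expect_true(all(c(a$q_s, a$q_a, a$q_m) >= 0 &
                      c(a$q_s, a$q_a, a$q_m) <= 1))
  }
  # p_s is nondecreasing in both mutation routes
  ps_u <- vapply(c(0, 1e-3, 1e-2, 5e-2),
                 function(u) extinction_probabilities(melanoma(u = u))$p_s,
                 numeric(1))
  expect_true(all(diff(ps_u) >= 0))
  ps_v <- vapply(c(1e-8, 1e-7, 1e-6),
                 function(v) extinction_probabilities(melanoma(v = v))$p_s,
                 numeric(1))
  expect_true(all(diff(ps_v) >= 0))
})

test_that("rescue probability behaves like 1 - (1 - p_s)^N", {
  p <- melanoma()
  expect_equal(rescue_probability(p, 0), 0)
  # defining property of the threshold size N* = 1/p_s
  p_s <- extinction_probabilities(p)$p_s
  expect_equal(rescue_probability(p, round(1 / p_s)), 1 - exp(-1),
               tolerance = 0.01)
  # monotone nondecreasing in N
  probs <- rescue_probability(p, 10^seq(4, 9, by = 0.5))
  expect_true(all(diff(probs) >= 0))
  # approximate form sums both mutational paths in the tolerant regime
  expect_equal(rescue_probability(p, 1e7, method = "approx"),
               -expm1(-(1e7 / 4e7 + 1e7 / as.numeric(threshold_aneuploid(p)))),
               tolerance = 1e-12)
  expect_equal(rescue_probability(p, 1e7, method = "approx"), 0.918,
               tolerance = 1e-3)
})

test_that("threshold sizes reproduce the published magnitudes", {
  p <- melanoma()
  expect_equal(threshold_direct(p), (0.04 / (1e-7 * 0.1)) * (0.1 / 0.01))
  expect_equal(threshold_direct(p), 4e7)
  # explicit 1/v scaling
  expect_equal(threshold_direct(melanoma(v = 2e-7)), 2e7)
  # log10 agreement with the exact PGF threshold at u = 0
  exact <- 1 / extinction_probabilities(melanoma(u = 0))$p_s
  expect_lt(abs(log10(4e7) - log10(exact)), 0.1)

  # aneuploid-path threshold, all three branches
  na_tol <- threshold_aneuploid(p)
  expect_equal(attr(na_tol, "branch"), "tolerant")
  expect_equal(as.numeric(na_tol),
               (0.04 / (1e-2 * 0.1)) * (1e-4 / (1e-7 * 0.0899)) * 10)
  expect_equal(signif(as.numeric(na_tol), 3), 4.45e6)

  p_st <- melanoma(lambda_a = 0.09)  # r_a = 0 exactly
  na_st <- threshold_aneuploid(p_st)
  expect_equal(attr(na_st, "branch"), "stationary")
  expect_equal(as.numeric(na_st), 40 * sqrt(0.1 / (1e-7 * 0.01)))
  expect_equal(as.numeric(na_st), 4e5)

  p_res <- melanoma(lambda_a = 0.095)
  na_res <- threshold_aneuploid(p_res)
  expect_equal(attr(na_res, "branch"), "resistant")
  expect_equal(as.numeric(na_res), 40 * (0.095 / 0.005))
  expect_equal(as.numeric(na_res), 760)

  # when aneuploidy cannot help, the direct threshold is returned
  na_dir <- threshold_aneuploid(melanoma(u = 0))
  expect_equal(attr(na_dir, "branch"), "direct")
  expect_equal(as.numeric(na_dir), 4e7)
})

test_that("threshold ratios are internally consistent and match printed values", {
  p <- melanoma()
  r <- threshold_ratios(p)
  expect_equal(round(r$ratio_aneuploid_direct, 2), 0.11)
  expect_equal(r$ratio_standing_aneuploid, (1e-2 / 1e-3) * (0.07 / 0.04))
  expect_equal(r$ratio_standing_aneuploid, 17.5)
  expect_equal(trunc(r$ratio_standing_direct * 100) / 100, 1.94)
  # consistency identity to machine precision
  expect_equal(r$ratio_standing_direct,
               r$ratio_standing_aneuploid * r$ratio_aneuploid_direct)
  # no preference between routes when the rates and costs coincide
  expect_equal(threshold_ratios(melanoma(u_pre = 1e-2, c = 0.04))$ratio_standing_aneuploid,
               1)
})

test_that("ratio branches equal the quotient of the threshold formulas", {
  cases <- list(tolerant = 0.0899, stationary = 0.09, resistant = 0.095)
  for (nm in names(cases)) {
    p <- melanoma(lambda_a = cases[[nm]])
    r_ad <- threshold_ratios(p)$ratio_aneuploid_direct
    quotient <- as.numeric(threshold_aneuploid(p)) / threshold_direct(p)
    expect_equal(r_ad, quotient, tolerance = 1e-14)
    ra <- p$lambda_a - p$mu_a
    printed <- switch(nm,
      tolerant = abs(ra) / (p$u * p$lambda_a),
      stationary = (1 / p$u) * sqrt(p$v_a * 0.01 / p$lambda_m),
      resistant = (p$v_a * 0.01 / p$lambda_m) * (p$lambda_a / (p$u * ra)))
    expect_equal(r_ad, printed, tolerance = 1e-12)
  }
})

test_that("deterministic trajectories solve the mean-field equations", {
  p <- melanoma()
  tr0 <- deterministic_trajectory(p, 1e7, 0)
  expect_equal(unlist(tr0[, -1], use.names = FALSE), c(1e7, 0, 0))
  # no missegregation: no aneuploids, ever
  trn <- deterministic_trajectory(melanoma(u = 0), 1e7, c(0, 10, 100))
  expect_true(all(trn$a_bar == 0))
  # aneuploid wave peaks where rs exp(rs t) = ra exp(ra t)
  t_peak <- log(-0.04 / -1e-4) / (-1e-4 - (-0.04))
  opt <- stats::optimize(function(t) deterministic_trajectory(p, 1e7, t)$a_bar,
                         c(1, 1e4), maximum = TRUE)
  expect_equal(opt$maximum, t_peak, tolerance = 1e-3)
  # closed-form mutant mean agrees with numeric quadrature to 1e-8 relative
  for (tt in c(50, 500, 5000)) {
    quad <- stats::integrate(function(tau) {
      dt <- deterministic_trajectory(p, 1e7, tau)
      exp(0.01 * (tt - tau)) * (1e-7 * 0.1 * dt$s_bar + 1e-7 * 0.0899 * dt$a_bar)
    }, 0, tt, rel.tol = 1e-10)$value
    closed <- deterministic_trajectory(p, 1e7, tt)$m_bar
    expect_equal(closed, quad, tolerance = 1e-8)
  }
})

test_that("rescue hazard obeys its closed-form identities", {
  p <- melanoma()
  h <- rescue_hazard(p, 1e7)
  expect_equal(h$Lambda(0), 0)
  tg <- seq(0, 5e4, length.out = 50)
  expect_true(all(diff(h$Lambda(tg)) >= 0))
  # machine-precision identity with the threshold sizes (tolerant branch)
  expect_equal(h$Lambda_inf,
               1e7 / threshold_direct(p) + 1e7 / as.numeric(threshold_aneuploid(p)),
               tolerance = 1e-12)
  expect_equal(h$Lambda_inf, 2.497, tolerance = 1e-3)
  # single-path limit
  h0 <- rescue_hazard(melanoma(u = 0), 1e7)
  expect_equal(h0$Lambda_inf, 1e7 / 4e7, tolerance = 1e-12)
  # hazard refuses regimes where aneuploid lineages are stochastic
  expect_error(rescue_hazard(melanoma(lambda_a = 0.095), 1e7),
               "unsupported regime")
})

test_that("mean rescue time hits its asymptotes and integrates in between", {
  p <- melanoma()
  small <- mean_rescue_time(p, 1e5)
  expect_equal(as.numeric(small), 25 + 1e4)
  expect_equal(attr(small, "method"), "asymptotic_small_N")
  expect_equal(as.numeric(mean_rescue_time(melanoma(u = 0), 1e5)), 25)
  big <- mean_rescue_time(p, 1e10)
  expect_equal(as.numeric(big), (1 / (1e-7 * 0.1 * 1e10)) * (0.1 / 0.01))
  expect_equal(as.numeric(big), 0.1)
  mid <- mean_rescue_time(p, 1e7)
  expect_equal(attr(mid, "method"), "hazard_integral")
  expect_gt(as.numeric(mid), as.numeric(big))
  expect_lt(as.numeric(mid), as.numeric(small))
})

test_that("recurrence and detection times follow the published branches", {
  p <- melanoma()
  small <- mean_recurrence_time(p, 1e5)
  expect_equal(as.numeric(small), 25 + 1e4 + log(0.1 * 1e5) / 0.01)
  large <- mean_recurrence_time(p, 1e10)
  expect_equal(as.numeric(large), 100 * log(0.05 / 1e-8))
  expect_equal(round(as.numeric(large)), 1542)
  expect_equal(attr(large, "method"), "asymptotic_large_N")
  # faster mutant growth shortens every branch
  p_fast <- melanoma(lambda_m = 0.12)
  expect_lt(as.numeric(mean_recurrence_time(p_fast, 1e5)), as.numeric(small))
  expect_lt(as.numeric(mean_recurrence_time(p_fast, 1e10)), as.numeric(large))
  mcs <- mean_recurrence_time(p, 1e6, method = "monte_carlo",
                              n_draws = 500, seed = 1)
  expect_lt(as.numeric(mean_recurrence_time(p_fast, 1e6, method = "monte_carlo",
                                            n_draws = 500, seed = 1)),
            as.numeric(mcs))

  # detection: same machinery, so M = target = N coincides with recurrence
  expect_equal(as.numeric(mean_detection_time(p, 1e5, 1e5)),
               as.numeric(small))
  # large tumors are detected before they regrow to full size
  det <- mean_detection_time(p, 1e10, 1e7)
  expect_lt(as.numeric(det), as.numeric(large))
  expect_equal(attr(det, "method"), "ode")
  # a single established cell marks the rescue event itself
  m1 <- mean_detection_time(p, 1e5, 1)
  expect_equal(as.numeric(m1), 25 + 1e4 + log(0.1) / 0.01)
})

test_that("survival curves are proper survival functions", {
  p <- melanoma()
  s <- rescue_time_survival(p, 1e7, t_grid = seq(0, 1e5, length.out = 100))
  expect_equal(s$survival[1], 1)
  expect_true(all(diff(s$survival) <= 1e-12))
  # complementarity at late times: plateau at 1 - p_rescue
  expect_equal(s$survival[100], exp(-rescue_hazard(p, 1e7)$Lambda_inf),
               tolerance = 1e-3)
  sc <- rescue_time_survival(p, 1e7, t_grid = c(0, 1e3, 1e5),
                             conditioned = TRUE)
  expect_equal(sc$survival[1], 1)
  expect_lt(sc$survival[3], 1e-3)

  rs <- recurrence_survival(p, 1e6, t_grid = seq(0, 5e4, length.out = 40),
                            n_draws = 400, seed = 8)
  expect_equal(rs$survival[1], 1)
  expect_true(all(diff(rs$survival) <= 1e-12))
  expect_true(all(rs$ci_lo <= rs$survival & rs$survival <= rs$ci_hi))
})

test_that("the analytic time layer refuses stationary and resistant regimes", {
  expect_error(mean_rescue_time(melanoma(lambda_a = 0.095), 1e6),
               "unsupported regime")
  expect_error(mean_recurrence_time(melanoma(lambda_a = 0.08999), 1e6),
               "unsupported regime")
})

test_that("lineage Monte-Carlo matches SSA on a scaled instance", {
  # independent cross-validation of the Poisson-lineage construction
  # against the exact simulator, at a size where both are feasible
  p <- scaled_direct(1000)
  ens <- run_replicates(p, 500, base_seed = 18,
                        stop = stop_rule(recurrence_target = 1000))
  rec <- ens$recurrence_time[ens$outcome == "recurred"]
  expect_gt(length(rec), 50)

  # (i) arrival times: SSA rescue times vs the sampled lineage arrivals
  arr <- aneurescue:::sample_rescue_arrivals(p, 1000, 2000, seed = 17)
  first <- vapply(arr, min, numeric(1))
  ssa_arr <- ens$rescue_time[ens$outcome == "recurred"]
  se_arr <- sqrt(stats::var(first) / length(first) +
                   stats::var(ssa_arr) / length(ssa_arr))
  expect_lt(abs(mean(first) - mean(ssa_arr)), 4 * se_arr)

  # (ii) recurrence times: the deterministic (1/p_m) exp(r_m t) lineage
  # growth replaces the random survivor amplitude W (E[W] = 1/p_m), whose
  # log-mean is offset by Euler-Mascheroni gamma; the construction is
  # therefore expected to sit within ~gamma/r_m below the SSA mean
  mc <- mean_recurrence_time(p, 1000, method = "monte_carlo",
                             n_draws = 2000, seed = 17)
  d <- derived_rates(p)
  se <- sqrt(attr(mc, "se")^2 + stats::var(rec) / length(rec))
  expect_gt(mean(rec) - as.numeric(mc), -4 * se)
  expect_lt(mean(rec) - as.numeric(mc), 0.5772157 / d$r_m + 4 * se)
  expect_lt(abs(as.numeric(mc) - mean(rec)) / mean(rec), 0.2)
})
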