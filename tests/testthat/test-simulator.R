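test_that("event rates substitute the parameter table into the event channels", {
  er <- event_rates(melanoma(), s = 1, a = 0, m = 0)
  expect_equal(nrow(er), 9)
  get <- function(e) er$rate[er$event == e]
  expect_equal(get("sensitive_birth"), 0.1)
  expect_equal(get("sensitive_death"), 0.14)
  expect_equal(get("missegregation"), 1e-3)
  expect_equal(get("sensitive_mutation"), 1e-8)

  # absorbing extinction state
  expect_true(all(event_rates(melanoma(), 0, 0, 0)$rate == 0))

  # at s = K the logistic effective sensitive death rate is mu_s + lambda_s
  pk <- melanoma(carrying_capacity = 1e4)
  erk <- event_rates(pk, s = 1e4, a = 0, m = 0)
  expect_equal(erk$rate[erk$event == "sensitive_death"], (0.14 + 0.1) * 1e4)

  # exact division factors restore (1 - u - v)
  ex <- event_rates(melanoma(), 10, 10, 0, exact_division_factors = TRUE)
  expect_equal(ex$rate[ex$event == "sensitive_birth"],
               0.1 * 10 * (1 - 1e-2 - 1e-7))
  expect_equal(ex$rate[ex$event == "aneuploid_birth"],
               0.0899 * 10 * (1 - 1e-7))
})

test_that("establishment threshold solves the joint-extinction condition", {
  expect_equal(mutant_establishment_threshold(melanoma()), 66L)
  # direct check of the defining inequality (0.9)^66 < 1e-3 <= (0.9)^65
  expect_lt(0.9^66, 1e-3)
  expect_gte(0.9^65, 1e-3)
  p2 <- suppressWarnings(melanoma(mu_m = 0.001))
  expect_equal(mutant_establishment_threshold(p2), 2L)
  expect_lt((0.001 / 0.1)^2, 1e-3)
  p3 <- suppressWarnings(melanoma(mu_m = 0))
  expect_equal(mutant_establishment_threshold(p3), 1L)
  expect_error(mutant_establishment_threshold(suppressWarnings(melanoma(mu_m = 0.2))),
               "cannot establish")
})

test_that("degenerate and subcritical runs terminate as expected", {
  # empty initial state is absorbed immediately
  tr <- simulate_tumor(melanoma(), seed = 1,
                       init = tibble::tibble(s = 0, a = 0, m = 0))
  expect_equal(attr(tr, "outcome"), "extinct")
  expect_equal(tr$t[nrow(tr)], 0)

  # without any rescue path a subcritical population always dies
  p <- melanoma(u = 0, v = 0, n_init = 50)
  ens <- run_replicates(p, 200, base_seed = 5)
  expect_true(all(ens$outcome == "extinct"))
  expect_true(all(ens$final_s == 0 & ens$final_a == 0 & ens$final_m == 0))
})

test_that("runs are bit-reproducible and ensembles derive seeds deterministically", {
  p <- scaled_direct(400)
  t1 <- simulate_tumor(p, seed = 33)
  t2 <- simulate_tumor(p, seed = 33)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "outcome"), attr(t2, "outcome"))

  e1 <- run_replicates(p, 5, base_seed = 12)
  e2 <- run_replicates(p, 5, base_seed = 12)
  expect_identical(as.data.frame(e1), as.data.frame(e2))

  # a one-replicate ensemble is exactly one run with the derived seed
  single <- simulate_tumor(p, seed = e1$seed[1], record_interval = Inf)
  expect_equal(e1$final_s[1], unname(attr(single, "final_state")["s"]))
  expect_equal(e1$outcome[1] == "rescued",
               attr(single, "outcome") == "rescued")
})

test_that("event bookkeeping conserves counts genotype by genotype", {
  p <- rescue_preset("melanoma_a375", v = 1e-3, n_init = 300)
  for (seed in c(2, 3, 4)) {
    tr <- simulate_tumor(p, seed = seed)
    ev <- attr(tr, "event_counts")
    fin <- attr(tr, "final_state")
    expect_equal(unname(fin["s"]),
                 300 + unname(ev["sensitive_birth"] - ev["sensitive_death"]))
    expect_equal(unname(fin["a"]),
                 unname(ev["missegregation"] + ev["aneuploid_birth"] -
                          ev["aneuploid_death"]))
    expect_equal(unname(fin["m"]),
                 unname(ev["sensitive_mutation"] + ev["aneuploid_mutation"] +
                          ev["mutant_birth"] - ev["mutant_death"]))
    # counts along the trajectory never go negative
    expect_true(all(tr$s >= 0 & tr$a >= 0 & tr$m >= 0))
    expect_true(!is.unsorted(tr$t))
  }
})

test_that("standing-variation initialization matches the balance fraction", {
  expect_equal(initial_state(melanoma(u_pre = 0)),
               tibble::tibble(s = 1e7, a = 0, m = 0))
  exp_state <- initial_state(melanoma(), mode = "expected")
  expect_equal(exp_state$a, round(1e-3 * 0.1 / 0.07 * 1e7))  # 14,286 cells
  expect_equal(exp_state$s + exp_state$a, 1e7)
  expect_equal(exp_state$m, 0)

  # binomial draws center on f * N
  p <- melanoma(n_init = 1e5)
  f <- derived_rates(p)$f_standing
  set.seed(81)
  draws <- replicate(1000, initial_state(p, mode = "stochastic")$a)
  se <- sqrt(1e5 * f * (1 - f) / 1000)
  expect_lt(abs(mean(draws) - f * 1e5), 3 * se)
})

test_that("tau-leaping clamps at zero and reproduces the linear birth-death mean", {
  # pure-death channel: counts are nonincreasing and reach zero
  pd <- suppressWarnings(rescue_params(
    lambda_s = 0, mu_s = 0.5, lambda_a = 0, mu_a = 0.5, lambda_m = 0.1,
    mu_m = 0.05, u = 0, v = 0, c = 0.07, n_init = 200))
  tr <- simulate_tumor(pd, seed = 9, method = "tau", tau_step = 0.1,
                       stop = stop_rule(establishment = 0, max_time = 100))
  expect_true(all(diff(tr$s) <= 0))
  expect_equal(tr$s[nrow(tr)], 0)

  # ensemble mean of s at t = 50 agrees with N exp(r_s t)
  p <- melanoma(u = 0, v = 0, n_init = 1000)
  finals <- vapply(1:400, function(i) {
    tr <- simulate_tumor(p, seed = 9000 + i, method = "tau", tau_step = 0.1,
                         stop = stop_rule(establishment = 0, max_time = 50.05),
                         record_interval = Inf)
    unname(attr(tr, "final_state")["s"])
  }, numeric(1))
  expected <- 1000 * exp(-0.04 * 50)
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("SSA rescue frequency agrees with the branching-process fixed point", {
  p <- scaled_direct(1000)
  ens <- run_replicates(p, 400, base_seed = 21)
  p_theory <- rescue_probability(p, 1000)
  p_hat <- mean(ens$outcome == "rescued")
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / 400)
  expect_lt(abs(p_hat - p_theory), half + 1e-9)
})

test_that("an infinite carrying capacity reproduces the density-independent model", {
  base <- melanoma(u = 0, v = 0, n_init = 30)
  withk <- melanoma(u = 0, v = 0, n_init = 30, carrying_capacity = 1e15)
  for (seed in 1:20) {
    t0 <- simulate_tumor(base, seed = seed,
                         stop = stop_rule(establishment = 0, max_time = 1e4))
    t1 <- simulate_tumor(withk, seed = seed,
                         stop = stop_rule(establishment = 0, max_time = 1e4))
    expect_equal(t0$s, t1$s)
    expect_equal(attr(t0, "final_state"), attr(t1, "final_state"))
  }
})
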