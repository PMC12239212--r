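test_that("presets reproduce the published parameter tables", {
  p <- melanoma()
  expect_equal(p$lambda_s, 0.1)
  expect_equal(p$mu_s, 0.14)
  expect_equal(p$lambda_a, 0.0899)
  expect_equal(p$mu_a, 0.09)
  expect_equal(p$lambda_m, 0.1)
  expect_equal(p$mu_m, 0.09)
  expect_equal(p$u, 1e-2)
  expect_equal(p$u_pre, 1e-3)
  expect_equal(p$v, 1e-7)
  expect_equal(p$v_a, 1e-7)  # defaults to v
  expect_equal(p$c, 0.07)
  expect_equal(p$n_init, 1e7)

  # TNBC clones share division rates and differ only in aneuploid death rate
  for (nm in c("tnbc_sa609", "tnbc_sa1035", "tnbc_sa535")) {
    q <- rescue_preset(nm)
    expect_equal(q$lambda_s, 0.0845)
    expect_equal(q$lambda_a, 0.0845)
    expect_equal(q$lambda_m, 0.0845)
    expect_equal(q$mu_s, 0.1215)
    expect_equal(q$mu_m, 0.076)
  }
  expect_equal(rescue_preset("tnbc_sa609")$mu_a, 0.076)
  expect_equal(rescue_preset("tnbc_sa1035")$mu_a, 0.1015)
  expect_equal(rescue_preset("tnbc_sa535")$mu_a, 0.1115)

  expect_error(rescue_preset("nope"), "melanoma_a375")
  expect_equal(melanoma(lambda_a = 0.095)$lambda_a, 0.095)
  expect_error(melanoma(bogus = 1), "bogus")
})

test_that("parameter invariants are enforced", {
  expect_error(melanoma(u = -0.1), "\\[0, 1\\)")
  expect_error(melanoma(v = 1.5), "\\[0, 1\\)")
  expect_error(melanoma(mu_s = Inf), "finite")
  expect_error(melanoma(n_init = 0), "positive")
  # non-declining sensitive population is flagged, not fatal
  expect_warning(melanoma(mu_s = 0.05), "not declining")
})

test_that("derived rates match hand-computed values", {
  d <- derived_rates(melanoma())
  expect_equal(d$r_s, -0.04)
  expect_equal(d$r_a, -1e-4)
  expect_equal(d$r_m, 0.01)
  expect_equal(d$p_m, 0.1)
  # T* = sqrt(lambda_m / (v_a r_m)) / (2 lambda_a) = 1e4 / 0.1798
  expect_equal(d$t_star, 1e4 / (2 * 0.0899), tolerance = 1e-12)
  expect_equal(d$ra_tstar, -1e-4 * 1e4 / (2 * 0.0899), tolerance = 1e-12)
  expect_equal(d$f_standing, 1e-3 * 0.1 / 0.07, tolerance = 1e-12)

  expect_error(derived_rates(suppressWarnings(melanoma(mu_m = 0.2))),
               "mutant not resistant")
  expect_error(derived_rates(melanoma(c = 1e-9, u_pre = 0.5)),
               "must be < 1")
})

test_that("aneuploidy cost recovers the selection coefficient", {
  expect_equal(aneuploidy_cost(0.15, 24), abs(log(0.15 / 0.85)) / 24)
  expect_equal(round(aneuploidy_cost(0.15, 24), 2), 0.07)
  expect_equal(aneuploidy_cost(0.5, 100), 0)       # no change from 1:1
  expect_equal(aneuploidy_cost(0.25, 10), log(3) / 10)
  expect_error(aneuploidy_cost(0, 24), "degenerate")
  expect_error(aneuploidy_cost(1, 24), "degenerate")
})

test_that("regime classification follows the branch conditions", {
  expect_equal(as.character(classify_regime(melanoma(u = 0))$regime),
               "direct_mutation")
  expect_equal(as.character(classify_regime(melanoma())$regime), "tolerant")
  expect_equal(as.character(classify_regime(melanoma(lambda_a = 0.08999))$regime),
               "stationary")
  expect_equal(as.character(classify_regime(melanoma(lambda_a = 0.095))$regime),
               "resistant")
  # published TNBC bounds: SA609 resistant (ra T* > 500), the others carry a
  # strongly tolerant aneuploid phenotype (ra T* < -1000); for those two,
  # missegregation is too rare relative to the decline (u lambda_a < -r_a)
  # for the tolerant path to matter, so the rescue route is direct mutation
  r609 <- classify_regime(rescue_preset("tnbc_sa609"))
  expect_equal(as.character(r609$regime), "resistant")
  expect_gt(r609$ra_tstar, 500)
  for (nm in c("tnbc_sa1035", "tnbc_sa535")) {
    r <- classify_regime(rescue_preset(nm))
    expect_equal(as.character(r$aneuploid_phenotype), "tolerant")
    expect_lt(r$ra_tstar, -1000)
    expect_equal(as.character(r$regime), "direct_mutation")
    expect_lt(r$u_lambda_a, r$neg_r_a)
  }
})

test_that("classification is invariant under rescaling time units", {
  set.seed(7)
  for (k in c(0.1, 2, 10)) {
    for (nm in c("melanoma_a375", "tnbc_sa609", "tnbc_sa1035")) {
      p <- rescue_preset(nm)
      ps <- suppressWarnings(rescue_params(
        lambda_s = p$lambda_s * k, mu_s = p$mu_s * k,
        lambda_a = p$lambda_a * k, mu_a = p$mu_a * k,
        lambda_m = p$lambda_m * k, mu_m = p$mu_m * k,
        u = p$u, u_pre = p$u_pre, v = p$v, v_a = p$v_a,
        c = p$c * k, n_init = p$n_init))
      expect_equal(derived_rates(ps)$t_star, derived_rates(p)$t_star / k,
                   tolerance = 1e-12)
      expect_equal(derived_rates(ps)$ra_tstar, derived_rates(p)$ra_tstar,
                   tolerance = 1e-12)
      expect_equal(as.character(classify_regime(ps)$regime),
                   as.character(classify_regime(p)$regime))
    }
  }
})

test_that("tenfold aneuploid mutation rate shrinks T* by sqrt(10) and the tolerant threshold tenfold", {
  p1 <- melanoma()
  p10 <- melanoma(v_a = 1e-6)
  expect_equal(derived_rates(p1)$t_star / derived_rates(p10)$t_star,
               sqrt(10), tolerance = 1e-12)
  # still tolerant after the boost, so the threshold scales as 1/v_a
  expect_equal(as.character(classify_regime(p10)$regime), "tolerant")
  ratio <- as.numeric(threshold_aneuploid(p1)) /
    as.numeric(threshold_aneuploid(p10))
  expect_equal(ratio, 10, tolerance = 1e-10)
})

test_that("TNBC fitness back-calculation documents the published discrepancy", {
  tab <- tnbc_rates_from_fitness()
  expect_equal(tab$lambda[1], log(2) / 8.2, tolerance = 1e-12)
  # recomputed sensitive death rate is ~0.1220, not the stored 0.1215
  expect_gt(tab$mu_s[1], 0.1216)
  expect_lt(tab$mu_s[1], 0.1224)
  expect_equal(rescue_preset("tnbc_sa609")$mu_s, 0.1215)
})
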