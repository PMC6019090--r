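test_that("the sampler matches the conjugate closed form when the hump is fixed", {
  # with dopt and sigma fixed and a flat prior, the Gmax posterior is normal
  # with mean sum(w*y)/sum(w^2) and sd sigma/sqrt(sum(w^2))
  rec <- tiny_records(n = 120, seed = 31)
  truth <- attr(rec, "truth")$params
  fit <- fit_growth_model(
    rec, model0_spec(),
    priors = list(gmax_base = prior_flat(), theta = prior_normal(),
                  dopt = prior_loguniform(), sigma = prior_halfcauchy()),
    mcmc = quick_mcmc(seed = 9, iterations = 4000),
    fixed = list(dopt = truth$dopt, sigma = truth$sigma))
  w <- exp(-0.5 * log(rec$dbh_t0 / truth$dopt)^2)
  y <- log(rec$agr + 1)
  m_true <- sum(w * y) / sum(w^2)
  s_true <- truth$sigma / sqrt(sum(w^2))
  draws <- fit$draws$gmax_base
  mc_se <- s_true / sqrt(fit$ess[["gmax_base"]])
  expect_lt(abs(mean(draws) - m_true), 3 * mc_se)
  expect_lt(abs(sd(draws) - s_true), 3 * s_true / sqrt(fit$ess[["gmax_base"]]))
})

test_that("identical seed and config reproduce the draws exactly", {
  rec <- tiny_records(n = 60, seed = 12)
  f1 <- fit_growth_model(rec, mcmc = quick_mcmc(seed = 3))
  f2 <- fit_growth_model(rec, mcmc = quick_mcmc(seed = 3))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$point, f2$point)
  f3 <- fit_growth_model(rec, mcmc = quick_mcmc(seed = 4))
  expect_false(identical(f1$draws$gmax_base, f3$draws$gmax_base))
})

test_that("posterior draws respect parameter support and carry diagnostics", {
  rec <- tiny_records(n = 80, seed = 13)
  fit <- fit_growth_model(rec, mcmc = quick_mcmc(seed = 5))
  expect_true(all(fit$draws$sigma > 0))
  expect_true(all(fit$draws$dopt > 0))
  expect_true(all(fit$draws$dopt >= 2 & fit$draws$dopt <= 200))
  s <- posterior_summary(fit)
  expect_equal(nrow(s), length(fit$free))
  expect_true(all(s$lower <= s$upper))
  expect_true(all(is.finite(s$rhat)) && all(is.finite(s$ess)))
  expect_true(all(fit$acceptance > 0.05 & fit$acceptance < 0.95))
  # the reported point is the retained draw of maximum likelihood
  expect_equal(unname(fit$point[fit$free]),
               unlist(fit$draws[which.max(fit$draws$loglik), fit$free],
                      use.names = FALSE))
})

test_that("summaries are stable under record permutation", {
  rec <- tiny_records(n = 80, seed = 14)
  set.seed(1); perm <- sample(nrow(rec))
  f1 <- fit_growth_model(rec, mcmc = quick_mcmc(seed = 6))
  f2 <- fit_growth_model(rec[perm, ], mcmc = quick_mcmc(seed = 6))
  s1 <- posterior_summary(f1); s2 <- posterior_summary(f2)
  expect_equal(s1$mean, s2$mean, tolerance = 0.05)
  expect_equal(s1$lower, s2$lower, tolerance = 0.1)
})

test_that("interval-excludes-zero reads the central 95% interval", {
  f <- fake_fit(list(b = rexp(4000) + 0.01))
  expect_true(credible_interval_excludes_zero(f, "b"))
  set.seed(2)
  f2 <- fake_fit(list(b = rnorm(4000)))
  expect_false(credible_interval_excludes_zero(f2, "b"))
  expect_error(credible_interval_excludes_zero(f2, "c"), "unknown parameter")
})

test_that("degenerate model terms and bad records are refused", {
  rec <- tiny_records(n = 40, seed = 15)
  rec$prun <- 0.5  # nobody varies
  expect_error(fit_growth_model(rec, model1_spec(), mcmc = quick_mcmc()),
               "zero variance")
  expect_error(fit_growth_model(tiny_records(40, 1)[1:5, ],
                                mcmc = quick_mcmc()),
               "at least 10")
  expect_error(mcmc_config(chains = 1), "chains")
  expect_error(mcmc_config(iterations = 1500, burn_fraction = 0.5), "1000")
})

test_that("split-Rhat and ESS behave sensibly on known chains", {
  set.seed(8)
  good <- replicate(4, rnorm(1000), simplify = FALSE)
  expect_lt(split_rhat(good), 1.02)
  expect_gt(ess_autocorr(good), 2000)
  # separated chains must be flagged
  bad <- list(rnorm(1000, 0), rnorm(1000, 5), rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(split_rhat(bad), 1.5)
  # heavy autocorrelation shrinks the effective sample
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.95), 1000)),
                  simplify = FALSE)
  expect_lt(ess_autocorr(ar), 1000)
})

test_that("WAIC penalizes added noise parameters on null data", {
  rec <- generate_tree_records(tiny_config(n = 200, seed = 16))
  f0 <- fit_growth_model(rec, model0_spec(), mcmc = quick_mcmc(seed = 2))
  f1 <- fit_growth_model(rec, model1_spec(), mcmc = quick_mcmc(seed = 2))
  w0 <- waic(f0, rec); w1 <- waic(f1, rec)
  expect_gt(w1$p_waic, w0$p_waic)
  expect_true(is.finite(w0$waic) && is.finite(w1$waic))
})
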