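test_that("the mean function peaks at dopt and is log-symmetric", {
  p <- growth_params(0.36, 8.76, 0.51)
  expect_equal(mean_log_agr(8.76, p), 0.36)
  expect_equal(mean_log_agr(8.76 * exp(1), p), 0.36 * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(mean_log_agr(8.76 * exp(1), p), 0.21835, tolerance = 1e-5)
  expect_equal(mean_log_agr(8.76 / exp(1), p),
               mean_log_agr(8.76 * exp(1), p), tolerance = 1e-12)
  # properties over random parameter sets: peak dominance and symmetry
  set.seed(11)
  for (i in 1:20) {
    pp <- growth_params(runif(1, 0.1, 1), runif(1, 3, 40), runif(1, 0.2, 1))
    r <- runif(1, 1.01, 6)
    expect_equal(mean_log_agr(pp$dopt * r, pp), mean_log_agr(pp$dopt / r, pp),
                 tolerance = 1e-12)
    dbh <- exp(runif(30, log(2), log(120)))
    expect_true(all(mean_log_agr(pp$dopt, pp) >= mean_log_agr(dbh, pp)))
  }
  expect_error(mean_log_agr(0, p), "dbh")
  expect_error(mean_log_agr(-3, p), "dbh")
})

test_that("Gmax linear predictor reproduces the published arithmetic", {
  # no covariates: base unchanged
  expect_equal(gmax_linear(growth_params(0.36, 8.76, 0.51), model0_spec()),
               0.36)
  # disturbance model: full pruning shifts Gmax by theta_P
  p1 <- growth_params(0.44, 8.76, 0.51, c(debark = 0.12, prun = -0.24))
  expect_equal(gmax_linear(p1, model1_spec(), list(debark = 0, prun = 1)),
               0.20)
  # interaction model: at wd z = 1.5 the pruning terms cancel exactly
  p3 <- growth_params(0.41, 8.76, 0.51,
                      c(prun = -0.18, wd = -0.10, "prun:wd" = 0.12))
  expect_equal(gmax_linear(p3, model3_spec(), list(prun = 1, wd = 1.5)),
               0.41 - 0.18 - 0.15 + 0.18)
  expect_equal(gmax_linear(p3, model3_spec(), list(prun = 1, wd = 1.5)),
               gmax_linear(p3, model3_spec(), list(prun = 0, wd = 1.5)),
               tolerance = 1e-12)
  expect_error(gmax_linear(p1, model1_spec(), list(debark = 0)), "prun")
  expect_error(gmax_linear(p1, model1_spec(), list(debark = 0, prun = 45)),
               "percent")
})

test_that("models with zero coefficients reduce exactly to the size-only model", {
  dbh <- exp(seq(log(2), log(80), length.out = 25))
  p0 <- growth_params(0.36, 8.76, 0.51)
  for (sp in list(model1_spec(), model2_spec(), model3_spec())) {
    th <- setNames(rep(0, length(spec_terms(sp))), spec_terms(sp))
    pz <- growth_params(0.36, 8.76, 0.51, th)
    cov <- list(debark = 0.4, prun = 0.7, wd = 1.2, lma = -0.5)
    expect_equal(mean_log_agr(dbh, pz, sp, cov), mean_log_agr(dbh, p0),
                 tolerance = 1e-12)
  }
})

test_that("model spec construction enforces heredity and known terms", {
  expect_error(growth_model_spec("prun", "prun:wd"), "heredity")
  expect_error(growth_model_spec(c("prun", "prun")), "duplicated")
  expect_error(growth_model_spec("height"), "unknown covariate")
  expect_error(growth_model_spec(c("wd", "lma"), "wd:lma"),
               "unknown interaction")
  expect_identical(spec_terms(model3_spec()), c("prun", "wd", "prun:wd"))
  expect_length(spec_terms(model0_spec()), 0)
})

test_that("log-likelihood matches an independent density-sum oracle", {
  p <- growth_params(0.36, 8.76, 0.51)
  # single record sitting exactly at its mean
  mu <- mean_log_agr(5, p)
  rec1 <- data.frame(tree_id = "x", dbh_t0 = 5, agr = exp(mu) - 1)
  expect_equal(log_likelihood(rec1, p),
               -0.5 * log(2 * pi * 0.51^2), tolerance = 1e-12)
  # 20 random records against a from-scratch normal-density summation
  set.seed(21)
  rec <- data.frame(tree_id = sprintf("t%d", 1:20),
                    dbh_t0 = exp(runif(20, log(2), log(60))),
                    agr = runif(20, -0.3, 2))
  oracle <- sum(vapply(seq_len(20), function(i) {
    m <- 0.36 * exp(-0.5 * (log(rec$dbh_t0[i]) - log(8.76))^2)
    y <- log(rec$agr[i] + 1)
    -0.5 * log(2 * pi) - log(0.51) - (y - m)^2 / (2 * 0.51^2)
  }, numeric(1)))
  expect_equal(log_likelihood(rec, p), oracle, tolerance = 1e-10)
  # additivity and permutation invariance
  expect_equal(log_likelihood(rec, p),
               log_likelihood(rec[1:10, ], p) + log_likelihood(rec[11:20, ], p),
               tolerance = 1e-10)
  expect_equal(log_likelihood(rec[sample(20), ], p), log_likelihood(rec, p),
               tolerance = 1e-10)
  bad <- rec; bad$agr[3] <- -1
  expect_error(log_likelihood(bad, p), "t3")
})

test_that("simulated growth honours the model and its support", {
  p <- growth_params(0.36, 8.76, 0.51)
  # degenerate-noise limit reproduces the back-transformed mean
  p_small <- growth_params(0.36, 8.76, 1e-12)
  expect_equal(simulate_agr(c(3, 8.76, 40), p_small, seed = 1),
               exp(mean_log_agr(c(3, 8.76, 40), p)) - 1, tolerance = 1e-9)
  # seeded determinism
  expect_identical(simulate_agr(1:10 + 1, p, seed = 5),
                   simulate_agr(1:10 + 1, p, seed = 5))
  # Monte-Carlo mean of log(agr+1) within 3 SE of the model mean
  n <- 1e5
  draws <- simulate_agr(rep(8.76, n), p, seed = 42)
  expect_true(all(draws > -1))
  expect_equal(mean(log(draws + 1)), 0.36,
               tolerance = 3 * 0.51 / sqrt(n) / 0.36 + 1e-9)
})
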