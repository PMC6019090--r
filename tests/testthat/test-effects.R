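p_model3 <- function() {
  growth_params(0.41, 8.76, 0.51,
                c(prun = -0.18, wd = -0.10, "prun:wd" = 0.12))
}

test_that("the zero-cost wood density reproduces the published threshold", {
  wd0 <- zero_cost_wd(p_model3(), default_wd_standardization())
  expect_lt(abs(wd0 - 0.73), 0.005)
  # degenerate and error branches
  p_null <- growth_params(0.41, 8.76, 0.51,
                          c(prun = 0, wd = -0.1, "prun:wd" = 0))
  out <- zero_cost_wd(p_null, default_wd_standardization())
  expect_equal(as.numeric(out), 0.56)
  expect_true(attr(out, "degenerate"))
  p_noint <- growth_params(0.41, 8.76, 0.51,
                           c(prun = -0.18, wd = -0.1, "prun:wd" = 0))
  expect_error(zero_cost_wd(p_noint, default_wd_standardization()),
               "never vanishes")
})

test_that("the pruning-cost surface behaves as the model dictates", {
  std <- default_wd_standardization()
  dbh <- seq(2, 60, by = 2)
  wd <- seq(0.35, 0.85, by = 0.05)
  # no pruning coefficients, no cost anywhere
  p0 <- growth_params(0.41, 8.76, 0.51,
                      c(prun = 0, wd = -0.10, "prun:wd" = 0))
  g0 <- pruning_cost(p0, std, dbh, wd)
  expect_true(all(abs(g0$cost) < 1e-12))
  # at the z = 1.5 wood density the pruning terms cancel for every diameter
  wd_cancel <- std$mean + 1.5 * std$sd
  g1 <- pruning_cost(p_model3(), std, dbh, c(wd_cancel - 1e-9, wd_cancel))
  expect_true(all(abs(g1$cost[, 2]) < 1e-9))
  # cost peaks at intermediate size: dopt beats 4*dopt for low-WD trees
  g2 <- pruning_cost(p_model3(), std, c(8.76, 4 * 8.76), c(0.40, 0.45))
  expect_true(all(g2$cost[1, ] > g2$cost[2, ]))
  # the cost changes sign across the zero-cost threshold
  thr <- zero_cost_wd(p_model3(), std)
  g3 <- pruning_cost(p_model3(), std, 8.76, c(thr - 0.05, thr + 0.05))
  expect_gt(g3$cost[1, 1], 0)
  expect_lt(g3$cost[1, 2], 0)
  expect_error(pruning_cost(growth_params(0.4, 8, 0.5), std, dbh, wd),
               "prun")
  expect_error(pruning_cost(p_model3(), std, c(3, 2), wd), "increasing")
})

test_that("the reserve comparison equals a textbook pooled t-test", {
  x <- c(0.5, 0.6, 0.7); y <- c(0.6, 0.7, 0.8)
  rec <- data.frame(wd = c(x, y), in_reserve = rep(c(FALSE, TRUE), each = 3))
  r <- reserve_wd_test(rec)
  # hand-computed pooled-variance formulas
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(r$difference, -0.1)
  expect_equal(r$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-10)
  # random-input agreement with the same formulas
  set.seed(33)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1), 0.55, 0.1)
    b <- rnorm(sample(5:40, 1), 0.50, 0.1)
    rr <- reserve_wd_test(data.frame(
      wd = c(a, b), in_reserve = rep(c(FALSE, TRUE), c(length(a), length(b)))))
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_o <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(rr$statistic, t_o, tolerance = 1e-10)
    expect_equal(rr$p_value, 2 * pt(-abs(t_o), na + nb - 2),
                 tolerance = 1e-10)
  }
  # identical groups: no difference, p = 1
  same <- data.frame(wd = rep(0.5, 6), in_reserve = rep(c(TRUE, FALSE), 3))
  r0 <- reserve_wd_test(same)
  expect_equal(r0$difference, 0)
  expect_equal(r0$p_value, 1)
  expect_error(reserve_wd_test(data.frame(wd = 1:3,
                                          in_reserve = c(TRUE, TRUE, TRUE))),
               ">= 2 trees")
  # Welch flag reaches the unequal-variance test: fractional df under
  # unequal spreads
  rw <- reserve_wd_test(data.frame(
    wd = c(0.50, 0.55, 0.60, 0.52, 0.20, 0.90, 0.45, 0.75),
    in_reserve = rep(c(FALSE, TRUE), each = 4)), welch = TRUE)
  expect_equal(rw$method, "welch")
  expect_false(isTRUE(all.equal(rw$df, 6)))
})

test_that("binned growth summaries partition the data with Tukey whiskers", {
  rec <- data.frame(dbh_t0 = rep(10, 5), agr = c(1, 2, 3, 4, 5))
  b <- binned_agr_summary(rec, n_bins = 1)
  expect_equal(b$table$q1, 2)
  expect_equal(b$table$median, 3)
  expect_equal(b$table$q3, 4)
  expect_length(b$outliers[["1"]], 0)
  # degenerate: identical growth everywhere, zero-width box
  same <- data.frame(dbh_t0 = runif(30, 2, 50), agr = rep(0.4, 30))
  bs <- binned_agr_summary(same, n_bins = 4)
  expect_true(all(bs$table$q1 == 0.4 & bs$table$q3 == 0.4))
  expect_equal(sum(lengths(bs$outliers)), 0)
  # conservation and whisker/outlier partition on random data
  rec2 <- generate_tree_records(tiny_config(n = 200, seed = 17))
  b2 <- binned_agr_summary(rec2, n_bins = 8)
  expect_equal(sum(b2$table$n), 200)
  for (i in seq_len(nrow(b2$table))) {
    row <- b2$table[i, ]
    n_out <- length(b2$outliers[[as.character(row$bin)]])
    expect_true(row$whisker_low >= row$q1 - 1.5 * (row$q3 - row$q1) - 1e-12)
    expect_true(row$whisker_high <= row$q3 + 1.5 * (row$q3 - row$q1) + 1e-12)
    expect_true(row$q1 <= row$median && row$median <= row$q3)
  }
  expect_error(binned_agr_summary(rec2[0, ]), "no records")
})

test_that("posterior trajectories bracket their median and match the cost", {
  rec <- generate_tree_records(tiny_config(n = 150, seed = 18,
                                           growth_truth = truth_model3()))
  fit <- fit_growth_model(rec, model3_spec(), mcmc = quick_mcmc(seed = 21))
  grid <- c(3, 8.76, 20, 50)
  tr <- predicted_trajectory(fit, grid, covariates = list(prun = 0, wd = 0),
                             n_draws = 200)
  expect_true(all(tr$lower <= tr$median & tr$median <= tr$upper))
  # definitional consistency: unpruned minus pruned prediction at the point
  # parameters equals the pruning-cost surface there
  pp <- point_params(fit)
  std <- fit$spec$standardization$wd
  wd_raw <- 0.45
  z <- (wd_raw - std$mean) / std$sd
  diff_curve <- predict_agr(grid, pp, fit$spec, list(prun = 0, wd = z)) -
    predict_agr(grid, pp, fit$spec, list(prun = 1, wd = z))
  cost <- pruning_cost(pp, std, grid, wd_raw)
  expect_equal(diff_curve, cost$cost[, 1], tolerance = 1e-12)
})
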