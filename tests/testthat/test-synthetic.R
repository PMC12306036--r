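test_that("stored curvatures satisfy the identifiability constraints", {
  cfg <- sim_config()
  for (nm in c("age", "period", "cohort")) {
    v <- cfg$curv[[nm]]
    t_ <- seq_along(v)
    expect_lt(abs(sum(v)), 1e-10)
    expect_lt(abs(sum(t_ * v)), 1e-10)
  }
})

test_that("the true linear predictor is additive with injectable pieces", {
  cfg0 <- sim_config(curv_scale = c(age = 0, period = 0, cohort = 0),
                     slope_age = 0, slope_period = 0)
  eta0 <- sim_true_eta(cfg0)$single$eta
  expect_equal(max(eta0) - min(eta0), 0) # constant rate surface
  expect_equal(eta0[1], cfg0$shift)
  # doubling the scales doubles the curvature part of eta cell-wise
  cfg1 <- sim_config(curv_scale = c(age = 0.3, period = 0.1, cohort = 0.2))
  cfg2 <- sim_config(curv_scale = 2 * c(age = 0.3, period = 0.1, cohort = 0.2))
  base <- sim_config(curv_scale = c(age = 0, period = 0, cohort = 0))
  f1 <- sim_true_eta(cfg1)$single$eta - sim_true_eta(base)$single$eta
  f2 <- sim_true_eta(cfg2)$single$eta - sim_true_eta(base)$single$eta
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("simulated counts are Poisson draws at the configured rates", {
  cfg <- sim_config(ages = 40:44, periods = 2001:2003, agg_width = 5,
                    fit_end = 2003)
  truth <- sim_true_eta(cfg)$single
  rate1 <- cfg$population * exp(truth$eta[1])
  draws <- vapply(1:2000, function(s) sim_counts(cfg, seed = s)$deaths[1],
                  numeric(1))
  se <- sqrt(rate1 / 2000)
  expect_lt(abs(mean(draws) - rate1), 3 * se)
  # determinism
  expect_identical(sim_counts(cfg, seed = 7), sim_counts(cfg, seed = 7))
  expect_false(identical(sim_counts(cfg, seed = 7), sim_counts(cfg, seed = 8)))
  # a vanishing rate gives all-zero counts
  cfg0 <- sim_config(ages = 40:44, periods = 2001:2003, shift = -60,
                     fit_end = 2003)
  expect_true(all(sim_counts(cfg0, seed = 1)$deaths == 0))
})

test_that("per-cell dispersion is Poisson-like, and overdispersed for NB", {
  cfg <- sim_config(ages = 40:44, periods = 2001:2002, agg_width = 5,
                    fit_end = 2002)
  draws <- vapply(1:400, function(s) sim_counts(cfg, seed = s)$deaths,
                  numeric(10))
  idx <- apply(draws, 1, var) / apply(draws, 1, mean)
  expect_lt(mean(idx), 1.3)
  expect_gt(mean(idx), 0.7)
  cfg_nb <- sim_config(ages = 40:44, periods = 2001:2002, agg_width = 5,
                       fit_end = 2002, family = "negative_binomial",
                       nb_dispersion = 3)
  draws_nb <- vapply(1:400, function(s) sim_counts(cfg_nb, seed = s)$deaths,
                     numeric(10))
  idx_nb <- apply(draws_nb, 1, var) / apply(draws_nb, 1, mean)
  expect_gt(mean(idx_nb), 1.5)
})

test_that("age aggregation conserves counts and exposure at the stated midpoints", {
  cfg <- sim_config()
  d <- sim_counts(cfg, seed = 5)
  agg <- aggregate_ages(d, 5)
  expect_equal(sum(agg$deaths), sum(d$deaths))
  expect_equal(sum(agg$population), sum(d$population))
  expect_equal(sort(unique(agg$age)), seq(12.5, 82.5, by = 5))
  expect_true(all(agg$population == 5 * 750000))
  g <- attr(agg, "grid")
  expect_equal(g$M, 5L)
  expect_equal(g$I, 15L)
  # ragged bands are rejected
  expect_error(aggregate_ages(d[d$age >= 11, ], 5), "ragged")
})

test_that("parameter recovery holds for both smoothers on low-noise data", {
  cfg <- sim_config(population = 7.5e6) # 10x the default population
  d <- sim_apc_data(cfg, seed = 2)
  truth <- sim_true_eta(cfg)$aggregated
  g <- attr(d, "grid")
  dec <- decompose_eta(g, truth$eta_true[order(truth$a, truth$p)])
  fit <- apc_spline(d)
  cv <- curvatures(fit)
  td <- tidy(fit)
  for (nm in c("age", "period", "cohort")) {
    tr <- dec$curvatures[[nm]]
    est <- cv$estimate[cv$component == nm]
    expect_lt(sqrt(mean((est - tr)^2)), 0.05 * diff(range(tr)))
  }
  # slopes recovered within two standard errors
  expect_lt(abs(td$estimate[2] - dec$slopes[["age"]]), 2 * td$std.error[2])
  expect_lt(abs(td$estimate[3] - dec$slopes[["period"]]), 2 * td$std.error[3])
})
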