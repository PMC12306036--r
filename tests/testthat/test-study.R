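tiny_cfg <- function() {
  sim_config(ages = 30:54, periods = 2001:2010, population = 500000,
             agg_width = 5, fit_end = 2008,
             curv_scale = c(age = 0.5, period = 0.2, cohort = 0.2))
}

test_that("the study runner produces one score row per model, replicate, window", {
  cfg <- tiny_cfg()
  mods <- study_models(spline_bases = "cr", rw2_u = 1,
                       knots = c(age = 4, period = 5, cohort = 6))
  st <- run_simulation_study(cfg, mods, n_rep = 2, seed = 5,
                             mcmc = list(iter = 500, burnin = 150, thin = 2))
  expect_equal(nrow(st$replicate_scores), 2 * 2 * 2)
  expect_setequal(unique(st$replicate_scores$window),
                  c("estimation", "forecasting"))
  expect_equal(nrow(st$failures), 0L)
  # every grid cell is scored in exactly one window
  one_rep <- st$cell_scores[st$cell_scores$replicate == 1 &
                              st$cell_scores$model == "spline_cr", ]
  expect_equal(nrow(one_rep), 5 * 10)
  expect_equal(sum(one_rep$forecast), 5 * 2)
  expect_equal(nrow(unique(one_rep[, c("a", "p")])), nrow(one_rep))
})

test_that("identical study configuration and seed give identical score tables", {
  cfg <- tiny_cfg()
  mods <- study_models(spline_bases = "cr", rw2_u = 1,
                       knots = c(age = 4, period = 5, cohort = 6))
  st1 <- run_simulation_study(cfg, mods, n_rep = 2, seed = 9,
                              mcmc = list(iter = 400, burnin = 100, thin = 2))
  st2 <- run_simulation_study(cfg, mods, n_rep = 2, seed = 9,
                              mcmc = list(iter = 400, burnin = 100, thin = 2))
  expect_identical(st1$summary, st2$summary)
  expect_identical(st1$replicate_scores, st2$replicate_scores)
})

test_that("holdout cells never contribute to fitting", {
  cfg <- tiny_cfg()
  d <- sim_apc_data(cfg, seed = 3)
  d_fit <- as_apc_data(d[d$period <= cfg$fit_end, ])
  # spline: altering holdout-window counts must not change the fit
  d_alt <- d
  d_alt$deaths[d_alt$period > cfg$fit_end] <- 0L
  r1 <- run_real_data(d, fit_end = cfg$fit_end, knots = c(4, 5, 6),
                      mcmc = list(iter = 400, burnin = 100, thin = 2), seed = 4)
  r2 <- run_real_data(d_alt, fit_end = cfg$fit_end, knots = c(4, 5, 6),
                      mcmc = list(iter = 400, burnin = 100, thin = 2), seed = 4)
  expect_identical(r1$spline$theta_hat, r2$spline$theta_hat)
  expect_identical(r1$rw2$eta_samples, r2$rw2$eta_samples)
  # rw2: NA pseudo-observations on the extended grid equal fitting the
  # truncated data with an explicit horizon
  d_na <- d
  d_na$deaths[d_na$period > cfg$fit_end] <- NA
  f_na <- apc_rw2(d_na, horizon = 0, iter = 400, burnin = 100, thin = 2,
                  seed = 11)
  f_tr <- apc_rw2(d_fit, horizon = 2, iter = 400, burnin = 100, thin = 2,
                  seed = 11)
  expect_equal(f_na$eta_samples, f_tr$eta_samples, tolerance = 1e-12)
})

test_that("the real-data workflow yields the 2 x 2 x 3 score layout", {
  cfg <- tiny_cfg()
  d <- sim_apc_data(cfg, seed = 6)
  res <- run_real_data(d, fit_end = cfg$fit_end, knots = c(4, 5, 6),
                       mcmc = list(iter = 500, burnin = 150, thin = 2), seed = 2)
  expect_equal(nrow(res$scores), 4L) # 2 models x 2 windows
  expect_setequal(res$scores$model, c("spline", "rw2"))
  expect_setequal(res$scores$window, c("estimation", "forecasting"))
  expect_true(all(c("is", "width", "coverage", "mae", "mse") %in%
                    names(res$scores)))
  expect_match(res$truth_convention, "0.5")
  # trajectories carry both models over all cells with intervals
  expect_equal(nrow(res$trajectories), 2 * nrow(d))
  expect_true(all(res$trajectories$lwr <= res$trajectories$upr))
})

test_that("a synthetic CSV round-trips through the real-data workflow", {
  cfg <- tiny_cfg()
  d <- sim_apc_data(cfg, seed = 8)
  path <- tempfile(fileext = ".csv")
  write_apc(d, path)
  res <- run_real_data(path, fit_end = cfg$fit_end, knots = c(4, 5, 6),
                       mcmc = list(iter = 400, burnin = 100, thin = 2), seed = 3)
  expect_s3_class(res, "apc_real")
  expect_equal(res$horizon, 2L)
})

test_that("model failures are recorded and excessive failure aborts the study", {
  cfg <- tiny_cfg()
  expect_error(study_models(spline_bases = character(0), rw2_u = numeric(0)),
               "empty")
  # an unfittable roster entry fails every replicate, tripping the 20% guard
  mods <- study_models(spline_bases = "cr", rw2_u = 1,
                       knots = c(age = 4, period = 5, cohort = 6))
  mods$basis[mods$type == "spline"] <- "no_such_basis"
  expect_error(
    run_simulation_study(cfg, mods, n_rep = 2, seed = 1,
                         mcmc = list(iter = 400, burnin = 100, thin = 2)),
    "20%"
  )
})
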