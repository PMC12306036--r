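test_that("lambda = 0 gaussian fit equals unpenalised least squares", {
  g <- apc_grid(0, 1, 5, 0, 1, 6)
  surf <- additive_surface(g)
  set.seed(3)
  d <- data.frame(age = surf$cells$age, period = surf$cells$period,
                  deaths = round(100 + 10 * surf$eta + rnorm(nrow(surf$cells))),
                  population = 1)
  fit <- apc_spline(d, basis = "cr", knots = c(4, 4, 5),
                    family = "gaussian", lambda = 0)
  ls <- stats::lm.fit(fit$design$X, d$deaths[order(d$age, d$period)])
  expect_equal(as.numeric(fit$design$X %*% fit$theta_hat),
               as.numeric(ls$fitted.values), tolerance = 1e-8)
})

test_that("very large lambda shrinks every curvature to zero", {
  g <- apc_grid(0, 1, 6, 0, 1, 8)
  d <- tiny_poisson(g, seed = 4)
  fit <- apc_spline(d, basis = "cr", knots = c(4, 5, 6), lambda = 1e8)
  cv <- curvatures(fit)
  expect_lt(max(abs(cv$estimate)), 1e-4)
  expect_lt(sum(fit$edf), 0.05)
})

test_that("PIRLS at fixed lambda matches a direct penalised-likelihood optimiser", {
  g <- apc_grid(0, 1, 5, 0, 1, 5)
  d <- tiny_poisson(g, seed = 3)
  lam <- c(age = 3, period = 7, cohort = 2)
  fit <- apc_spline(d, basis = "cr", knots = c(4, 4, 5), lambda = lam)
  des <- fit$design
  P <- apcsmooth:::design_penalty(des, as.list(lam))
  dd <- as_apc_data(d)
  m <- match(paste(des$cells$a, des$cells$p), paste(dd$a, dd$p))
  y <- dd$deaths[m]
  off <- log(dd$population[m])
  negpll <- function(th) {
    eta <- des$X %*% th
    -(sum(y * (eta + off) - exp(eta + off))) + drop(t(th) %*% P %*% th)
  }
  o <- optim(rep(0, ncol(des$X)), negpll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(o$par - fit$theta_hat)), 1e-6)
  expect_true(fit$converged)
})

test_that("smoothing selection drives pure noise to near-zero curvature EDF", {
  g <- apc_grid(0, 1, 8, 0, 1, 10)
  cells <- as_tibble(g)
  set.seed(11)
  d <- data.frame(age = cells$age, period = cells$period,
                  deaths = round(rnorm(nrow(cells), 100, 1)), population = 1)
  fit <- apc_spline(d, basis = "cr", knots = c(5, 5, 6), family = "gaussian")
  expect_true(all(fit$edf < 0.5))
})

test_that("smoothing selection tracks a strong smooth signal", {
  g <- apc_grid(0, 1, 10, 0, 1, 12)
  surf <- additive_surface(g, amp = c(1.5, 1.0, 1.2))
  set.seed(12)
  d <- data.frame(age = surf$cells$age, period = surf$cells$period,
                  deaths = surf$eta + rnorm(length(surf$eta), 0, 0.02),
                  population = 1)
  fit <- apc_spline(d, basis = "cr", knots = c(6, 6, 8), family = "gaussian",
                    theta = 0.02)
  eta_hat <- as.numeric(fit$design$X %*% fit$theta_hat)
  rmse <- sqrt(mean((eta_hat - surf$eta)^2))
  rmse_const <- sqrt(mean((mean(surf$eta) - surf$eta)^2))
  expect_lt(rmse * 10, rmse_const)
})

test_that("the selected smoothing parameter sits at a local criterion minimum", {
  d <- sim_fixture()
  fit <- apc_spline(d, knots = c(age = 4, period = 5, cohort = 6))
  # refit at perturbed lambdas: the criterion must not improve
  for (nm in c("age", "period", "cohort")) {
    for (fac in c(10^-0.5, 10^0.5)) {
      lam <- fit$lambda
      lam[[nm]] <- lam[[nm]] * fac
      alt <- apc_spline(d, knots = c(age = 4, period = 5, cohort = 6),
                        lambda = unlist(lam))
      expect_gte(alt$criterion_value, fit$criterion_value - 1e-6)
    }
  }
})

test_that("intervals are eta_hat plus/minus 1.96 standard errors", {
  d <- sim_fixture()
  fit <- apc_spline(d, knots = c(4, 5, 6), lambda = 10)
  pr <- predict(fit, level = 0.95)
  z <- qnorm(0.975)
  expect_equal(pr$upr, pr$eta + z * pr$se, tolerance = 1e-12)
  expect_equal(pr$lwr, pr$eta - z * pr$se, tolerance = 1e-12)
  # the printed example: eta 2.0, se 0.1 -> [1.804, 2.196]
  expect_equal(2 + c(-1, 1) * z * 0.1, c(1.804, 2.196), tolerance = 1e-3)
})

test_that("a fitted pure linear trend forecasts as its continuation", {
  g <- apc_grid(0, 1, 6, 0, 1, 8)
  cells <- as_tibble(g)
  eta <- 5 + 0.3 * cells$a - 0.2 * cells$p
  d <- data.frame(age = cells$age, period = cells$period,
                  deaths = eta, population = 1)
  fit <- apc_spline(d, basis = "cr", knots = c(4, 5, 6),
                    family = "gaussian", lambda = 1)
  pr <- predict(fit, horizon = 3)
  eta_ext <- 5 + 0.3 * pr$a - 0.2 * pr$p
  expect_lt(max(abs(pr$eta - eta_ext)), 1e-6)
})

test_that("a saturated gaussian lambda = 0 fit interpolates APC-additive data", {
  g <- apc_grid(0, 1, 5, 0, 1, 6)
  surf <- additive_surface(g)
  d <- data.frame(age = surf$cells$age, period = surf$cells$period,
                  deaths = surf$eta, population = 1)
  fit <- apc_spline(d, basis = "identity", family = "gaussian", lambda = 0)
  eta_hat <- as.numeric(fit$design$X %*% fit$theta_hat)
  expect_lt(max(abs(eta_hat - surf$eta)), 1e-8)
})

test_that("curvature EDF is non-increasing in its smoothing parameter", {
  d <- sim_fixture()
  lams <- 10^seq(-2, 6, by = 1)
  edf_age <- vapply(lams, function(l) {
    apc_spline(d, knots = c(4, 5, 6),
               lambda = c(age = l, period = 10, cohort = 10))$edf[["age"]]
  }, numeric(1))
  expect_true(all(diff(edf_age) < 1e-8))
})

test_that("negative-binomial fits estimate a positive dispersion", {
  g <- apc_grid(0, 1, 5, 0, 1, 6)
  surf <- additive_surface(g)
  set.seed(9)
  d <- data.frame(
    age = surf$cells$age, period = surf$cells$period,
    deaths = rnbinom(length(surf$eta), size = 8, mu = 1e5 * exp(surf$eta)),
    population = 1e5
  )
  fit <- apc_spline(d, basis = "cr", knots = c(4, 4, 5),
                    family = "negative_binomial", lambda = 10)
  expect_gt(fit$family$theta, 0)
  expect_true(fit$converged)
})

test_that("selection and intervals agree with an independent GAM REML oracle", {
  # the same Holford design handed to mgcv as parametric terms with block
  # penalties; REML selection there is an independent implementation of the
  # same estimator (its lambda differs by exactly this package's factor-2
  # penalty convention)
  cfg <- sim_config()
  d <- sim_apc_data(cfg, seed = 11, window = "fit")
  fit <- apc_spline(d)
  des <- fit$design
  X <- des$X
  dd <- as_apc_data(d)
  m <- match(paste(des$cells$a, des$cells$p), paste(dd$a, dd$p))
  y <- dd$deaths[m]
  off <- log(dd$population[m])
  q <- ncol(X)
  embed <- function(S, b) {
    M <- matrix(0, q, q)
    M[b, b] <- S
    M
  }
  PP <- list(X = list(
    embed(des$comps$age$St, des$blocks$age),
    embed(des$comps$period$St, des$blocks$period),
    embed(des$comps$cohort$St, des$blocks$cohort)
  ))
  gm <- mgcv::gam(y ~ 0 + X + offset(off), family = stats::poisson(),
                  paraPen = PP, method = "REML")
  cells <- apcsmooth:::predict_cells(des, 3)
  Xp <- apcsmooth:::design_rows(des, cells)
  eta_gam <- as.numeric(Xp %*% stats::coef(gm))
  se_gam <- sqrt(rowSums((Xp %*% stats::vcov(gm)) * Xp))
  pr <- predict(fit, horizon = 3)
  expect_lt(max(abs(pr$eta - eta_gam)), 5e-3)
  expect_lt(max(abs(pr$se / se_gam - 1)), 0.01)
})
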