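test_that("the RW2 structure matrix matches the printed stencil and D'D", {
  R5 <- as.matrix(rw2_structure(5))
  expect_equal(R5[3, ], c(1, -4, 6, -4, 1))
  expect_equal(R5[1, ], c(1, -2, 1, 0, 0))
  expect_equal(R5[2, ], c(-2, 5, -4, 1, 0))
  expect_equal(as.matrix(rw2_structure(3)),
               matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3))
  for (n in c(3, 4, 7, 12)) {
    R <- as.matrix(rw2_structure(n))
    expect_equal(R, oracle_structure(n))
    D <- diff(diag(n), differences = 2)
    expect_equal(R, crossprod(D))
    expect_lt(max(abs(R %*% rep(1, n))), 1e-12)
    expect_lt(max(abs(R %*% seq_len(n))), 1e-12)
  }
  expect_error(rw2_structure(2), "too short")
  # order 1 accepted for completeness
  expect_equal(as.matrix(rw2_structure(3, order = 1)),
               crossprod(diff(diag(3))))
})

test_that("the PC prior rate follows kappa = -log(alpha)/U and calibrates the tail", {
  expect_equal(pc_prior_rate(1, 0.01), -log(0.01), tolerance = 1e-12)
  expect_equal(pc_prior_rate(-log(0.37), 0.37), 1, tolerance = 1e-12)
  expect_error(pc_prior_rate(-1, 0.5))
  expect_error(pc_prior_rate(1, 1.5))
  # Monte-Carlo check of P(sigma > U) = alpha under sigma ~ Exp(kappa)
  set.seed(99)
  sig <- stats::rexp(1e6, rate = pc_prior_rate(3, 0.01))
  mc_se <- sqrt(0.01 * 0.99 / 1e6)
  expect_lt(abs(mean(sig > 3) - 0.01), 3 * mc_se)
})

test_that("the RW2 log prior density matches hand evaluation", {
  # linear field: zero second differences, only the normalising power remains
  for (tau in c(0.5, 2, 10)) {
    f <- 2 + 3 * (1:7)
    expect_equal(log_prior_rw2(f, tau), (7 - 2) / 2 * log(tau))
  }
  expect_equal(log_prior_rw2(c(0, 0, 1), 2), -1 + 0.5 * log(2))
  # quadratic-form identity: sum of squared second differences = f'Rf
  set.seed(5)
  for (r in 1:100) {
    n <- sample(3:20, 1)
    f <- rnorm(n)
    tau <- stats::rexp(1) + 0.1
    lhs <- log_prior_rw2(f, tau)
    R <- as.matrix(rw2_structure(n))
    rhs <- (n - 2) / 2 * log(tau) - tau / 2 * drop(t(f) %*% R %*% f)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("gaussian posterior at fixed tau matches dense closed-form conditioning", {
  g <- apc_grid(0, 1, 6, 0, 1, 7)
  surf <- additive_surface(g)
  set.seed(4)
  d <- data.frame(age = surf$cells$age, period = surf$cells$period,
                  deaths = surf$eta + rnorm(length(surf$eta), 0, 0.5),
                  population = 1)
  taus <- c(age = 2, period = 3, cohort = 4)
  mo <- apc_rw2(d, family = "gaussian", theta = 1, tau = taus, mode_only = TRUE)
  # dense oracle built from scratch: full precision + kriging-constrained mean
  I <- g$I; J <- g$J; K <- g$K
  mdim <- 3 + I + J + K
  cells <- as_tibble(g)
  X <- matrix(0, nrow(cells), mdim)
  X[, 1] <- 1
  X[, 2] <- cells$a - (I + 1) / 2
  X[, 3] <- cells$p - (J + 1) / 2
  bl <- list(3 + seq_len(I), 3 + I + seq_len(J), 3 + I + J + seq_len(K))
  X[cbind(seq_len(nrow(cells)), bl[[1]][cells$a])] <- 1
  X[cbind(seq_len(nrow(cells)), bl[[2]][cells$p])] <- 1
  X[cbind(seq_len(nrow(cells)), bl[[3]][cells$c])] <- 1
  A <- matrix(0, 6, mdim)
  for (k in 1:3) {
    A[2 * k - 1, bl[[k]]] <- 1
    A[2 * k, bl[[k]]] <- seq_along(bl[[k]])
  }
  P0 <- crossprod(A)
  diag(P0)[1:3] <- diag(P0)[1:3] + 1e-6
  for (k in 1:3) {
    D <- diff(diag(length(bl[[k]])), differences = 2)
    P0[bl[[k]], bl[[k]]] <- P0[bl[[k]], bl[[k]]] + taus[k] * crossprod(D)
  }
  Q <- crossprod(X) + P0
  mu <- solve(Q, crossprod(X, d$deaths))
  V <- solve(Q, t(A))
  mu_c <- mu - V %*% solve(A %*% V, A %*% mu)
  expect_lt(max(abs(mo$mode - mu_c)), 1e-6)

  # the sampled posterior mean agrees within Monte-Carlo error
  fit <- apc_rw2(d, family = "gaussian", theta = 1, tau = taus,
                 iter = 1500, burnin = 300, thin = 2, seed = 8)
  eta_mean <- rowMeans(fit$eta_samples)
  eta_closed <- as.numeric(X %*% mu_c)
  mcse <- apply(fit$eta_samples, 1, sd) / sqrt(ncol(fit$eta_samples))
  expect_true(all(abs(eta_mean - eta_closed) < 6 * mcse + 1e-8))
})

test_that("every retained sample honours the zero-sum and zero-trend constraints", {
  d <- sim_fixture()
  fit <- apc_rw2(d, iter = 600, burnin = 200, thin = 2, seed = 3)
  viol <- abs(fit$constraints %*% fit$x_samples)
  scale <- max(abs(fit$x_samples))
  expect_lt(max(viol), 1e-8 * max(scale, 1))
})

test_that("identical seed and configuration reproduce the samples exactly", {
  d <- sim_fixture()
  f1 <- apc_rw2(d, iter = 400, burnin = 100, thin = 1, seed = 21)
  f2 <- apc_rw2(d, iter = 400, burnin = 100, thin = 1, seed = 21)
  expect_identical(f1$eta_samples, f2$eta_samples)
  expect_identical(f1$tau_samples, f2$tau_samples)
  f3 <- apc_rw2(d, iter = 400, burnin = 100, thin = 1, seed = 22)
  expect_false(identical(f1$eta_samples, f3$eta_samples))
})

test_that("RW2 forecasting follows the linear-continuation / cubic-variance law", {
  set.seed(6)
  f <- cumsum(cumsum(rnorm(9, 0, 0.3)))
  tau <- 2.5
  fc <- rw2_forecast(f, tau, horizon = 4)
  n <- length(f)
  for (t in 1:4) {
    expect_equal(fc$mean[t], (1 + t) * f[n] - t * f[n - 1], tolerance = 1e-8)
    expect_equal(fc$var[t], t * (t + 1) * (2 * t + 1) / (6 * tau),
                 tolerance = 1e-8)
  }
  expect_error(rw2_forecast(f, tau, horizon = 0), "at least 1")
})

test_that("posterior summaries are ordered quantiles matching an independent formula", {
  d <- sim_fixture()
  fit <- apc_rw2(d, horizon = 2, iter = 700, burnin = 200, thin = 2, seed = 13)
  pr <- predict(fit)
  expect_true(all(pr$lwr <= pr$eta & pr$eta <= pr$upr))
  i <- 7
  s <- fit$eta_samples[i, ]
  expect_equal(pr$eta[i], manual_q(s, 0.5), tolerance = 1e-10)
  expect_equal(pr$lwr[i], manual_q(s, 0.025), tolerance = 1e-10)
  expect_equal(pr$upr[i], manual_q(s, 0.975), tolerance = 1e-10)
  # too few retained samples is an error
  small <- apc_rw2(d, iter = 260, burnin = 200, thin = 1, seed = 1)
  expect_error(predict(small), "at least 100")
})

test_that("forecast intervals widen with the horizon at fixed precision", {
  d <- sim_fixture()
  fit <- apc_rw2(d, horizon = 4, tau = c(age = 50, period = 50, cohort = 50),
                 iter = 1200, burnin = 200, thin = 2, seed = 17)
  pr <- predict(fit)
  gfit <- attr(as_apc_data(d), "grid")
  width_by_h <- tapply(pr$upr - pr$lwr, pmax(pr$p - gfit$J, 0), mean)
  expect_gt(width_by_h[["4"]], width_by_h[["1"]])
  expect_gt(width_by_h[["1"]], width_by_h[["0"]])
})

test_that("posterior medians cover a known truth on high-count data", {
  g <- apc_grid(0, 1, 6, 0, 1, 8)
  surf <- additive_surface(g, b0 = -6)
  set.seed(14)
  d <- data.frame(age = surf$cells$age, period = surf$cells$period,
                  deaths = rpois(length(surf$eta), 1e6 * exp(surf$eta)),
                  population = 1e6)
  fit <- apc_rw2(d, iter = 1200, burnin = 300, thin = 2, seed = 14)
  pr <- predict(fit)
  sd_post <- apply(fit$eta_samples, 1, sd)
  frac <- mean(abs(pr$eta - surf$eta) <= 3 * sd_post)
  expect_gte(frac, 0.95)
})

test_that("horizon = 0 produces a pure estimation fit with no forecast cells", {
  d <- sim_fixture()
  fit <- apc_rw2(d, horizon = 0, iter = 500, burnin = 150, thin = 2, seed = 2)
  expect_false(any(predict(fit)$forecast))
  expect_equal(nrow(fit$cells), nrow(d))
})
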