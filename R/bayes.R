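# Bayesian APC model with intrinsic RW2 priors on the three curvature fields,
# PC priors on the precisions, and MCMC inference:
#   (i)  the latent Gaussian block (slopes and all three fields jointly) is
#        updated with an independence Metropolis-Hastings proposal built from
#        the Gaussian approximation at the conditional mode (exact Gibbs when
#        the family is gaussian);
#   (ii) each precision tau_T gets a random-walk Metropolis step on log(tau)
#        under the PC prior, with step sizes adapted during burn-in only;
#   (iii) the two linear constraints per field (zero sum, zero linear trend)
#        are enforced by conditioning-by-kriging projection of each proposal.
# Forecasting extends the period and cohort fields; unobserved cells carry no
# likelihood contribution, so their linear-predictor posterior is the forecast.

solve_chol <- function(U, B) backsolve(U, backsolve(U, B, transpose = TRUE))

# Sparse incidence design mapping the latent vector
# x = (beta[3], f_age[I], f_period[Jp], f_cohort[Kp]) to eta over cells.
rw2_model_matrix <- function(cells, I, Jp, Kp, slopes, centres) {
  n <- nrow(cells)
  idx <- list(age = cells$a, period = cells$p, cohort = cells$c)
  Xf <- cbind(
    1,
    idx[[slopes[1]]] - centres[[slopes[1]]],
    idx[[slopes[2]]] - centres[[slopes[2]]]
  )
  offs <- c(3L, 3L + I, 3L + I + Jp)
  ji <- cbind(
    offs[1] + cells$a,
    offs[2] + cells$p,
    offs[3] + cells$c
  )
  m <- 3L + I + Jp + Kp
  Matrix::sparseMatrix(
    i = c(rep(seq_len(n), 3), rep(seq_len(n), 3)),
    j = c(rep(1:3, each = n), as.vector(ji)),
    x = c(as.vector(Xf), rep(1, 3 * n)),
    dims = c(n, m)
  )
}

#' Fit a Bayesian RW2 APC model by MCMC
#'
#' The identifiable APC model (intercept, two slopes, three curvature fields)
#' with independent intrinsic second-order random-walk priors on the age,
#' period and cohort fields, each constrained to zero sum and zero linear
#' trend (which fixes the rank-2 deficiency of the RW2 precision), vague
#' zero-mean Gaussian priors on the intercept and slopes, and penalised
#' complexity priors `P(sigma_T > U) = alpha` on the field precisions.
#' Count families use a `log(population)` offset.  With `horizon > 0` the
#' period and cohort fields are extended and the added cells are treated as
#' unobserved (no likelihood contribution); their posterior linear predictor
#' is the forecast, whose uncertainty grows cubically with the horizon under
#' the RW2 law.
#'
#' @param data Data frame with columns `age`, `period`, `deaths`,
#'   `population` ([as_apc_data()] is applied).  `deaths` may be `NA` for
#'   cells to predict.
#' @param horizon Forecast periods beyond the data (default 0).
#' @param pc_u,pc_alpha PC-prior contrast `P(sigma > pc_u) = pc_alpha` for
#'   every field precision (defaults 1 and 0.01).
#' @param family `"poisson"` (default), `"negative_binomial"` (supply
#'   `theta`), or `"gaussian"` (identity link; `theta` is the residual sd,
#'   default 1).
#' @param theta Family nuisance parameter, see `family`.
#' @param iter,burnin,thin Sampler budget: total iterations, burn-in
#'   discarded, thinning of the remainder (defaults 20000 / 5000 / 5).
#' @param seed Integer seed; identical seed and configuration reproduce the
#'   samples exactly.
#' @param drop_slope Which slope to omit (default `"cohort"`); posterior
#'   linear predictors are invariant to the choice.
#' @param tau Optional fixed precisions (single value or named
#'   age/period/cohort vector); skips the tau updates.
#' @param mode_only If `TRUE` (requires fixed `tau`), skip sampling and
#'   return the constrained conditional mode of the latent field under the
#'   Gaussian approximation (exact posterior mean/mode for the gaussian
#'   family).
#' @param beta_prec Prior precision of the intercept/slope block (default
#'   `1e-6`, i.e. variance `1e6`).
#' @return An object of class `apc_rw2` holding thinned posterior samples of
#'   the linear predictor, fields, slopes and precisions, plus diagnostics;
#'   or, if `mode_only`, a list with the latent mode and cell table.
#' @examples
#' d <- sim_fixture()
#' fit <- apc_rw2(d, iter = 600, burnin = 200, thin = 2, seed = 1)
#' glance(fit)
#' @export
apc_rw2 <- function(data, horizon = 0, pc_u = 1, pc_alpha = 0.01,
                    family = c("poisson", "negative_binomial", "gaussian"),
                    theta = NULL, iter = 20000, burnin = 5000, thin = 5,
                    seed = 1, drop_slope = c("cohort", "age", "period"),
                    tau = NULL, mode_only = FALSE, beta_prec = 1e-6) {
  fam <- apc_family(match.arg(family), theta)
  drop_slope <- match.arg(drop_slope)
  if (fam$name == "negative_binomial" && is.null(fam$theta)) {
    abort("Supply the negative-binomial dispersion `theta` for the Bayesian model.")
  }
  if (iter < burnin) abort("`iter` must be at least `burnin`.")
  data <- as_apc_data(data, check_counts = fam$name != "gaussian")
  grid0 <- attr(data, "grid")
  grid <- if (horizon > 0) extend_grid(grid0, horizon) else grid0
  I <- grid$I
  Jp <- grid$J
  Kp <- grid$K

  cells <- as_tibble(grid)
  key <- paste(data$a, data$p)
  m0 <- match(paste(cells$a, cells$p), key)
  cells$deaths <- data$deaths[m0]
  # forecast periods have no rows in `data`; carry the age-specific population
  pop_by_age <- vapply(seq_len(I), function(a) data$population[data$a == a][1], 1)
  cells$population <- ifelse(is.na(m0), pop_by_age[cells$a], data$population[m0])
  cells$forecast <- is.na(m0) | is.na(cells$deaths)
  y <- cells$deaths
  obs <- !is.na(y)
  if (!any(obs)) abort("No observed cells: nothing to fit.")
  off <- family_offset(fam, cells$population)

  slopes <- setdiff(c("age", "period", "cohort"), drop_slope)
  centres <- c(age = (I + 1) / 2, period = (Jp + 1) / 2, cohort = (Kp + 1) / 2)
  X <- rw2_model_matrix(cells, I, Jp, Kp, slopes, centres)
  mdim <- ncol(X)
  X_obs <- X[obs, , drop = FALSE]
  y_obs <- y[obs]
  off_obs <- off[obs]

  blocks <- list(
    beta = 1:3,
    age = 3L + seq_len(I),
    period = 3L + I + seq_len(Jp),
    cohort = 3L + I + Jp + seq_len(Kp)
  )
  flen <- c(age = I, period = Jp, cohort = Kp)

  # constraint matrix: zero sum and zero linear trend per field
  A <- matrix(0, 6, mdim)
  for (k in 1:3) {
    nm <- c("age", "period", "cohort")[k]
    A[2 * k - 1, blocks[[nm]]] <- 1
    A[2 * k, blocks[[nm]]] <- seq_len(flen[[nm]])
  }

  # embedded structure matrices and the fixed part of the prior precision
  R_emb <- lapply(c(age = "age", period = "period", cohort = "cohort"), function(nm) {
    R <- matrix(0, mdim, mdim)
    R[blocks[[nm]], blocks[[nm]]] <- as.matrix(rw2_structure(flen[[nm]]))
    R
  })
  P_fixed <- crossprod(A) # zero on the constraint set {Ax = 0}
  P_fixed[cbind(1:3, 1:3)] <- P_fixed[cbind(1:3, 1:3)] + beta_prec
  prior_prec <- function(tau_vec) {
    P_fixed + tau_vec[["age"]] * R_emb$age +
      tau_vec[["period"]] * R_emb$period + tau_vec[["cohort"]] * R_emb$cohort
  }

  kappa <- pc_prior_rate(pc_u, pc_alpha)
  fixed_tau <- !is.null(tau)
  tau_vec <- if (fixed_tau) {
    unlist(lambda_as_list(tau))
  } else {
    c(age = 1, period = 1, cohort = 1)
  }
  names(tau_vec) <- c("age", "period", "cohort")
  if (mode_only && !fixed_tau) abort("`mode_only = TRUE` requires fixed `tau`.")

  loglik_eta <- function(eta) family_loglik(fam, y_obs, eta[obs], off_obs)
  log_target <- function(x, P0) {
    eta <- as.numeric(X %*% x)
    loglik_eta(eta) - 0.5 * as.numeric(crossprod(x, P0 %*% x))
  }

  # Gaussian approximation at the conditional mode of the (ridged) surrogate
  gaussian_approx <- function(x_start, P0) {
    x <- x_start
    eta_o <- as.numeric(X_obs %*% x)
    for (nt in 1:50) {
      gh <- family_grad_hess(fam, y_obs, eta_o, off_obs)
      grad <- as.numeric(Matrix::crossprod(X_obs, gh$g)) - as.numeric(P0 %*% x)
      H <- as.matrix(Matrix::crossprod(X_obs * sqrt(gh$h))) + P0
      delta <- tryCatch(solve(H, grad), error = function(e) {
        solve(H + mean(diag(H)) * 1e-10 * diag(nrow(H)), grad)
      })
      step <- 1
      repeat {
        x_new <- x + step * delta
        eta_new <- as.numeric(X_obs %*% x_new)
        if (all(is.finite(eta_new)) && max(abs(eta_new)) < 500) break
        step <- step / 2
        if (step < 1e-8) break
      }
      x <- x_new
      eta_o <- eta_new
      if (max(abs(step * delta)) < 1e-10) break
      if (fam$name == "gaussian") break # quadratic: one step is exact
    }
    gh <- family_grad_hess(fam, y_obs, eta_o, off_obs)
    Q <- as.matrix(Matrix::crossprod(X_obs * sqrt(gh$h))) + P0
    list(mode = x, Q = Q, U = chol(Q))
  }

  # conditioning by kriging: project v onto {Av = 0} under precision Q
  make_projector <- function(U) {
    V <- solve_chol(U, t(A))
    W <- A %*% V
    function(v) as.numeric(v - V %*% solve(W, A %*% v))
  }

  set.seed(as.integer(seed %% .Machine$integer.max))

  # initial state: flat fields, intercept at the crude log-rate
  x <- numeric(mdim)
  x[1] <- if (fam$name == "gaussian") mean(y_obs) else
    log(sum(y_obs) / sum(cells$population[obs]))

  if (mode_only) {
    P0 <- prior_prec(tau_vec)
    ga <- gaussian_approx(x, P0)
    proj <- make_projector(ga$U)
    x_mode <- proj(ga$mode)
    return(list(
      mode = x_mode, eta = as.numeric(X %*% x_mode),
      blocks = blocks, cells = cells, tau = tau_vec
    ))
  }

  n_keep <- floor((iter - burnin) / thin)
  if (n_keep < 1) abort("Sampler budget keeps no samples; increase `iter`.")
  eta_s <- matrix(NA_real_, nrow(cells), n_keep)
  x_s <- matrix(NA_real_, mdim, n_keep)
  tau_s <- matrix(NA_real_, 3, n_keep, dimnames = list(c("age", "period", "cohort"), NULL))
  acc_latent <- 0L
  acc_tau <- c(age = 0L, period = 0L, cohort = 0L)
  prop_tau <- c(age = 0L, period = 0L, cohort = 0L)
  step_tau <- c(age = 1, period = 1, cohort = 1)
  adapt_acc <- c(age = 0L, period = 0L, cohort = 0L)
  adapt_n <- 0L

  P0 <- prior_prec(tau_vec)
  ga <- gaussian_approx(x, P0)
  proj <- make_projector(ga$U)
  # start at the constrained conditional mode: an independence proposal built
  # from the Gaussian approximation cannot escape a starting state far out in
  # the likelihood's sub-Gaussian tail, so begin inside the high-mass region
  x <- proj(ga$mode)
  lp_x <- log_target(x, P0)
  kept <- 0L

  for (it in seq_len(iter)) {
    if (!fixed_tau) {
      for (nm in c("age", "period", "cohort")) {
        f <- x[blocks[[nm]]]
        quad <- sum(diff(f, differences = 2)^2)
        rk <- flen[[nm]] - 2
        th <- log(tau_vec[[nm]])
        th_new <- th + step_tau[[nm]] * rnorm(1)
        lp_old <- rk / 2 * th - exp(th) / 2 * quad + pc_prior_log_density(th, kappa)
        lp_new <- rk / 2 * th_new - exp(th_new) / 2 * quad +
          pc_prior_log_density(th_new, kappa)
        if (it > burnin) prop_tau[[nm]] <- prop_tau[[nm]] + 1L
        if (log(runif(1)) < lp_new - lp_old) {
          tau_vec[[nm]] <- exp(th_new)
          if (it > burnin) acc_tau[[nm]] <- acc_tau[[nm]] + 1L
          if (it <= burnin) adapt_acc[[nm]] <- adapt_acc[[nm]] + 1L
        }
      }
      if (it <= burnin) {
        adapt_n <- adapt_n + 1L
        if (adapt_n %% 50 == 0) {
          rate <- adapt_acc / 50
          step_tau <- ifelse(rate > 0.5, step_tau * 1.3,
                             ifelse(rate < 0.3, step_tau / 1.3, step_tau))
          adapt_acc[] <- 0L
        }
      }
      P0 <- prior_prec(tau_vec)
      lp_x <- log_target(x, P0)
    }

    ga <- gaussian_approx(ga$mode, P0)
    proj <- make_projector(ga$U)
    z <- ga$mode + backsolve(ga$U, rnorm(mdim))
    x_prop <- proj(z)
    qform <- function(v) {
      d <- v - ga$mode
      -0.5 * sum((ga$U %*% d)^2)
    }
    lp_prop <- log_target(x_prop, P0)
    log_r <- (lp_prop - qform(x_prop)) - (lp_x - qform(x))
    if (log(runif(1)) < log_r) {
      x <- x_prop
      lp_x <- lp_prop
      if (it > burnin) acc_latent <- acc_latent + 1L
    }

    if (it > burnin && (it - burnin) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      x_s[, kept] <- x
      eta_s[, kept] <- as.numeric(X %*% x)
      tau_s[, kept] <- tau_vec
    }
  }

  n_post <- iter - burnin
  acc <- list(
    latent = acc_latent / n_post,
    tau = if (fixed_tau) NULL else acc_tau / pmax(prop_tau, 1)
  )
  # high acceptance is good for an independence proposal (1.0 is exact Gibbs
  # for the gaussian family); only a low rate signals a poor approximation
  if (acc$latent < 0.1) {
    warn(sprintf("Latent-block acceptance rate %.2f is very low.", acc$latent))
  }
  if (!fixed_tau && any(acc$tau < 0.1 | acc$tau > 0.9)) {
    warn(sprintf(
      "tau acceptance rates outside [0.1, 0.9] after adaptation: %s.",
      paste(sprintf("%s=%.2f", names(acc$tau), acc$tau), collapse = ", ")
    ))
  }

  structure(
    list(
      cells = cells, grid = grid, horizon = grid$horizon,
      family = fam, drop_slope = drop_slope, slopes = slopes,
      pc_u = pc_u, pc_alpha = pc_alpha, kappa = kappa,
      blocks = blocks, flen = flen,
      eta_samples = eta_s, x_samples = x_s,
      tau_samples = tau_s, fixed_tau = if (fixed_tau) tau_vec else NULL,
      acceptance = acc, step_tau = step_tau,
      iter = iter, burnin = burnin, thin = thin, n_keep = n_keep,
      seed = seed, beta_prec = beta_prec, constraints = A
    ),
    class = "apc_rw2"
  )
}

#' @export
print.apc_rw2 <- function(x, ...) {
  cat(sprintf(
    "<apc_rw2> %s family, PC prior U = %g, alpha = %g; slope dropped: %s\n",
    x$family$name, x$pc_u, x$pc_alpha, x$drop_slope
  ))
  cat(sprintf(
    "  %d iterations (%d burn-in, thin %d) -> %d samples; latent acceptance %.2f\n",
    x$iter, x$burnin, x$thin, x$n_keep, x$acceptance$latent
  ))
  if (x$horizon > 0) {
    cat(sprintf("  forecasting %d period(s)\n", x$horizon))
  }
  invisible(x)
}

#' Posterior summaries of the linear predictor
#'
#' Point predictions are the posterior median (50% quantile) of the per-cell
#' linear predictor; the interval is the 2.5% and 97.5% posterior quantiles
#' (for the default `level = 0.95`).
#'
#' @param object An [apc_rw2()] fit with at least 100 retained samples.
#' @param level Interval level (default 0.95).
#' @param ... Unused.
#' @return A tibble of class `apc_pred` with columns `age`, `period`, `a`,
#'   `p`, `c`, `eta` (posterior median), `lwr`, `upr`, `forecast`.
#' @export
predict.apc_rw2 <- function(object, level = 0.95, ...) {
  if (object$n_keep < 100) {
    abort(sprintf("Only %d retained samples; at least 100 are required.",
                  object$n_keep))
  }
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  qs <- t(apply(object$eta_samples, 1, quantile, probs = probs, names = FALSE))
  out <- object$cells[, c("a", "p", "c", "age", "period", "forecast")]
  out$eta <- qs[, 2]
  out$se <- apply(object$eta_samples, 1, sd)
  out$lwr <- qs[, 1]
  out$upr <- qs[, 3]
  attr(out, "level") <- level
  class(out) <- c("apc_pred", class(out))
  out
}

#' @rdname curvatures
#' @export
curvatures.apc_rw2 <- function(object, level = 0.95, ...) {
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  g <- object$grid
  labels <- list(
    age = g$age_values,
    period = g$period_values,
    cohort = seq_len(object$flen[["cohort"]])
  )
  purrr::map_dfr(c("age", "period", "cohort"), function(nm) {
    s <- object$x_samples[object$blocks[[nm]], , drop = FALSE]
    qs <- t(apply(s, 1, quantile, probs = probs, names = FALSE))
    tibble(
      component = nm, index = seq_len(object$flen[[nm]]),
      value = labels[[nm]],
      estimate = qs[, 2], se = apply(s, 1, sd), lwr = qs[, 1], upr = qs[, 3]
    )
  })
}

# simple initial-sequence effective sample size for a scalar chain
ess_chain <- function(v) {
  n <- length(v)
  if (n < 10 || sd(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  L <- if (length(pos)) pos[1] else length(ac)
  n / (1 + 2 * sum(ac[seq_len(L)]))
}

#' @method tidy apc_rw2
#' @export
tidy.apc_rw2 <- function(x, ...) {
  beta <- x$x_samples[1:3, , drop = FALSE]
  rows_beta <- purrr::map_dfr(1:3, function(i) {
    tibble(
      term = c("(Intercept)", paste0("slope_", x$slopes))[i],
      estimate = median(beta[i, ]),
      std.error = sd(beta[i, ]),
      conf.low = quantile(beta[i, ], 0.025, names = FALSE),
      conf.high = quantile(beta[i, ], 0.975, names = FALSE)
    )
  })
  rows_sigma <- purrr::map_dfr(c("age", "period", "cohort"), function(nm) {
    sig <- 1 / sqrt(x$tau_samples[nm, ])
    tibble(
      term = paste0("sigma_", nm),
      estimate = median(sig), std.error = sd(sig),
      conf.low = quantile(sig, 0.025, names = FALSE),
      conf.high = quantile(sig, 0.975, names = FALSE)
    )
  })
  dplyr::bind_rows(rows_beta, rows_sigma)
}

#' @method glance apc_rw2
#' @export
glance.apc_rw2 <- function(x, ...) {
  tibble(
    family = x$family$name,
    pc_u = x$pc_u, pc_alpha = x$pc_alpha,
    iter = x$iter, burnin = x$burnin, thin = x$thin,
    n_samples = x$n_keep,
    accept_latent = x$acceptance$latent,
    ess_tau_min = if (is.null(x$fixed_tau)) {
      min(apply(x$tau_samples, 1, ess_chain))
    } else NA_real_,
    seed = x$seed
  )
}
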