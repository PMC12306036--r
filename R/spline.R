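# Penalised regression-spline APC smoother: penalised IRLS at fixed smoothing
# parameters, smoothing-parameter selection (GCV / Laplace-approximate
# marginal likelihood), Bayesian-covariance intervals, and basis-extrapolation
# forecasting.

# Penalised iteratively reweighted least squares.  Maximises
#   l(theta) - theta' P theta
# (P = blockdiag(lambda_T * St_T), zero on fixed effects), i.e. the Newton
# system is (X'WX + 2P) theta = X'Wz.  Convergence: relative change in the
# penalised deviance D + 2 theta'P theta below `tol`.
pirls <- function(X, y, off, P, family, tol = 1e-8, maxit = 200) {
  ok <- !is.na(y)
  Xo <- X[ok, , drop = FALSE]
  yo <- y[ok]
  oo <- off[ok]
  if (sum(ok) < ncol(X) - qr(2 * P)$rank) {
    warn("Fewer observed cells than unpenalised coefficients; fit may be unstable.")
  }
  eta <- if (family$name == "gaussian") yo else log(yo + 0.5) - oo
  theta <- NULL
  pdev <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    irls <- family_irls(family, yo, eta, oo)
    A <- crossprod(Xo * sqrt(irls$w)) + 2 * P
    b <- crossprod(Xo, irls$w * irls$z)
    theta_new <- tryCatch(solve(A, b), error = function(e) qr.solve(A, b))
    eta_new <- as.numeric(Xo %*% theta_new)
    pdev_new <- family_deviance(family, yo, eta_new, oo) +
      2 * as.numeric(crossprod(theta_new, P %*% theta_new))
    # step halving towards the previous iterate if the objective worsened
    if (is.finite(pdev) && (!is.finite(pdev_new) || pdev_new > pdev + 1e-10)) {
      for (h in 1:30) {
        theta_new <- (theta_new + theta) / 2
        eta_new <- as.numeric(Xo %*% theta_new)
        pdev_new <- family_deviance(family, yo, eta_new, oo) +
          2 * as.numeric(crossprod(theta_new, P %*% theta_new))
        if (is.finite(pdev_new) && pdev_new <= pdev + 1e-10) break
      }
    }
    done <- is.finite(pdev) && abs(pdev - pdev_new) < tol * (abs(pdev_new) + 0.1)
    theta <- as.numeric(theta_new)
    eta <- eta_new
    pdev <- pdev_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  irls <- family_irls(family, yo, eta, oo)
  XtWX <- crossprod(Xo * sqrt(irls$w))
  A <- XtWX + 2 * P
  H_inv_XtWX <- solve(A, XtWX)
  list(
    theta = theta, eta = eta, obs = ok,
    A = A, XtWX = XtWX, Vb = solve(A),
    edf_diag = diag(H_inv_XtWX), edf = sum(diag(H_inv_XtWX)),
    deviance = family_deviance(family, yo, eta, oo),
    loglik = family_loglik(family, yo, eta, oo),
    penalty = as.numeric(crossprod(theta, P %*% theta)),
    pdev = pdev, iter = it, converged = converged,
    n_obs = sum(ok)
  )
}

lambda_as_list <- function(lambda) {
  if (is.null(names(lambda)) && length(lambda) == 3) {
    names(lambda) <- c("age", "period", "cohort")
  }
  if (length(lambda) == 1) {
    lambda <- c(age = lambda[[1]], period = lambda[[1]], cohort = lambda[[1]])
  }
  as.list(lambda[c("age", "period", "cohort")])
}

# Smoothing-selection criteria (smaller is better).
spline_criterion <- function(fit, family, lambda, design, criterion) {
  n <- fit$n_obs
  if (criterion == "gcv") {
    n * fit$deviance / (n - fit$edf)^2
  } else {
    # negative Laplace-approximate log marginal likelihood; terms constant in
    # lambda (log|St|, 2*pi powers) are dropped
    d <- vapply(design$comps, function(cc) ncol(cc$Zt), 1L)
    lam <- unlist(lambda[c("age", "period", "cohort")])
    ldetA <- determinant(fit$A, logarithm = TRUE)$modulus
    -(fit$loglik - fit$penalty + 0.5 * sum(d * log(lam)) - 0.5 * as.numeric(ldetA))
  }
}

fit_at_lambda <- function(X, y, off, design, family, lambda) {
  P <- design_penalty(design, lambda)
  pirls(X, y, off, P, family)
}

# Coordinate descent over log10(lambda_T): per-component grid search on
# [-4, 8] followed by golden-section refinement; ties broken toward larger
# lambda (the smoother fit).
select_lambda <- function(X, y, off, design, family, criterion,
                          grid = seq(-4, 8, length.out = 13), sweeps = 2) {
  lambda <- list(age = 1, period = 1, cohort = 1)
  profile <- list()
  crit_of <- function(lam) {
    fit <- fit_at_lambda(X, y, off, design, family, lam)
    spline_criterion(fit, family, lam, design, criterion)
  }
  for (sw in seq_len(sweeps)) {
    for (nm in c("age", "period", "cohort")) {
      vals <- vapply(grid, function(lg) {
        lam <- lambda
        lam[[nm]] <- 10^lg
        crit_of(lam)
      }, numeric(1))
      profile[[length(profile) + 1]] <- tibble(
        sweep = sw, component = nm, log10_lambda = grid, criterion = vals
      )
      finite <- is.finite(vals)
      if (!any(finite)) {
        abort(paste0(
          "Smoothing criterion non-finite over the entire grid for component '",
          nm, "'. Profile:\n",
          paste(sprintf("  log10(lambda)=%g -> %g", grid, vals), collapse = "\n")
        ))
      }
      best <- max(which(vals <= min(vals[finite]) + 1e-10)) # ties -> larger lambda
      lo <- grid[max(best - 1, 1)]
      hi <- grid[min(best + 1, length(grid))]
      opt <- optimize(function(lg) {
        lam <- lambda
        lam[[nm]] <- 10^lg
        crit_of(lam)
      }, lower = lo, upper = hi, tol = 0.02)
      cand <- c(grid[best], opt$minimum)
      cand_val <- c(vals[best], opt$objective)
      pick <- max(which(cand_val <= min(cand_val) + 1e-10))
      lambda[[nm]] <- 10^cand[pick]
    }
  }
  list(lambda = lambda, profile = dplyr::bind_rows(profile))
}

#' Fit a penalised-spline APC model
#'
#' Fits the identifiable APC model (intercept + two slopes + three constrained
#' curvature functions) with each curvature represented by a penalised spline
#' basis and an integrated-squared-second-derivative penalty, by penalised
#' iteratively reweighted least squares.  Count families use a
#' `log(population)` offset so the linear predictor is the log rate.
#' Smoothing parameters are selected by minimising GCV (gaussian family) or a
#' Laplace-approximate negative log marginal likelihood (count families)
#' unless `lambda` is supplied.
#'
#' @param data A data frame with columns `age`, `period`, `deaths`,
#'   `population` covering a full APC grid ([as_apc_data()] is applied).
#'   Cells with `deaths = NA` carry no likelihood contribution but are still
#'   predicted.
#' @param basis Spline basis for the curvatures: `"cr"` (cubic regression
#'   spline, default), `"bs"` (cubic B-spline), or `"identity"` (saturated,
#'   one coefficient per index with a second-difference penalty; cannot
#'   forecast beyond the fitted index set).
#' @param knots Named vector/list of knot counts, default
#'   `c(age = 10, period = 10, cohort = 12)`.  Counts exceeding a component's
#'   index length are reduced to it.
#' @param family `"poisson"` (default), `"negative_binomial"`, or
#'   `"gaussian"`.
#' @param theta Family nuisance parameter: negative-binomial dispersion
#'   (estimated by profile maximisation when `NULL`) or gaussian residual sd
#'   (default 1).
#' @param lambda Fixed smoothing parameters (single value or named
#'   age/period/cohort vector); `NULL` (default) selects them.
#' @param criterion `"gcv"` or `"laplace_reml"`; default by family.
#' @param drop_slope Which slope to omit from the design (default
#'   `"cohort"`); fitted linear predictors are invariant to this choice.
#' @param penalty `"deriv2"` (exact second-derivative penalty, default) or
#'   `"diff2"` (second-order coefficient-difference penalty).
#' @return An object of class `apc_spline`.
#' @examples
#' d <- sim_fixture()
#' fit <- apc_spline(d, knots = c(age = 4, period = 5, cohort = 6))
#' glance(fit)
#' @export
apc_spline <- function(data, basis = c("cr", "bs", "identity"),
                       knots = c(age = 10, period = 10, cohort = 12),
                       family = c("poisson", "negative_binomial", "gaussian"),
                       theta = NULL, lambda = NULL, criterion = NULL,
                       drop_slope = c("cohort", "age", "period"),
                       penalty = c("deriv2", "diff2")) {
  basis <- match.arg(basis)
  penalty <- match.arg(penalty)
  drop_slope <- match.arg(drop_slope)
  fam <- apc_family(match.arg(family), theta)
  data <- as_apc_data(data, check_counts = fam$name != "gaussian")
  grid <- attr(data, "grid")
  criterion <- criterion %||% if (fam$name == "gaussian") "gcv" else "laplace_reml"
  if (!criterion %in% c("gcv", "laplace_reml")) {
    abort("`criterion` must be 'gcv' or 'laplace_reml'.")
  }

  knots <- unlist(knots)
  if (is.null(names(knots))) names(knots) <- c("age", "period", "cohort")
  sizes <- c(age = grid$I, period = grid$J, cohort = grid$K)
  bases <- lapply(c(age = "age", period = "period", cohort = "cohort"), function(nm) {
    if (basis == "identity") {
      component_spec("identity", penalty = "diff2")
    } else {
      component_spec(basis, n_knots = min(knots[[nm]], sizes[[nm]]),
                     penalty = penalty)
    }
  })
  design <- apc_design(grid, drop_slope = drop_slope, bases = bases)

  cells <- design$cells
  key <- paste(data$a, data$p)
  m <- match(paste(cells$a, cells$p), key)
  y <- data$deaths[m]
  pop <- data$population[m]
  off <- family_offset(fam, pop)
  X <- design$X

  estimate_nb <- fam$name == "negative_binomial" && is.null(fam$theta)
  if (estimate_nb) fam$theta <- 10 # starting dispersion for selection

  profile <- NULL
  if (is.null(lambda)) {
    sel <- select_lambda(X, y, off, design, fam, criterion)
    lambda <- sel$lambda
    profile <- sel$profile
  } else {
    lambda <- lambda_as_list(lambda)
  }

  if (estimate_nb) {
    # profile the penalised log-likelihood over log(dispersion)
    opt <- optimize(function(lt) {
      f <- apc_family("negative_binomial", exp(lt))
      ft <- fit_at_lambda(X, y, off, design, f, lambda)
      -(ft$loglik - ft$penalty)
    }, lower = -4, upper = 12, tol = 1e-4)
    fam$theta <- exp(opt$minimum)
  }

  fit <- fit_at_lambda(X, y, off, design, fam, lambda)
  if (!fit$converged) {
    warn(sprintf(
      "PIRLS did not converge in %d iterations (last penalised deviance %.6g).",
      fit$iter, fit$pdev
    ))
  }
  if (any(abs(fit$theta) > 1e3 + abs(mean(fit$eta)))) {
    warn("Very large coefficient estimates: possible separation/infinite estimates.")
  }
  edf_comp <- vapply(c("age", "period", "cohort"), function(nm) {
    sum(fit$edf_diag[design$blocks[[nm]]])
  }, numeric(1))

  structure(
    list(
      design = design, family = fam, data = data,
      theta_hat = fit$theta, Vb = fit$Vb,
      lambda = lambda, criterion = criterion,
      criterion_value = spline_criterion(fit, fam, lambda, design, criterion),
      profile = profile,
      edf = edf_comp, edf_total = fit$edf,
      deviance = fit$deviance, loglik = fit$loglik,
      iter = fit$iter, converged = fit$converged,
      y = y, population = pop, offset = off
    ),
    class = "apc_spline"
  )
}

#' @export
print.apc_spline <- function(x, ...) {
  cat(sprintf(
    "<apc_spline> %s family, %s basis curvatures, slope dropped: %s\n",
    x$family$name, x$design$comps$age$kind, x$design$drop_slope
  ))
  cat(sprintf(
    "  lambda (age/period/cohort): %.3g / %.3g / %.3g;  EDF: %.2f / %.2f / %.2f\n",
    x$lambda$age, x$lambda$period, x$lambda$cohort,
    x$edf["age"], x$edf["period"], x$edf["cohort"]
  ))
  cat(sprintf(
    "  deviance %.4g on %d cells; %s = %.6g\n",
    x$deviance, sum(!is.na(x$y)), x$criterion, x$criterion_value
  ))
  invisible(x)
}

predict_cells <- function(design, horizon) {
  g <- design$grid
  Jp <- design$J_fit + horizon
  cells <- expand.grid(p = seq_len(Jp), a = seq_len(g$I))
  tibble(
    a = as.integer(cells$a), p = as.integer(cells$p),
    c = cohort_index(g, cells$a, cells$p),
    age = g$age_values[cells$a],
    period = g$period_start + g$period_width * (cells$p - 1),
    forecast = cells$p > design$J_fit
  )
}

#' Predict (and forecast) from a penalised-spline APC fit
#'
#' In-sample cells use the fitted design; forecast cells (periods beyond the
#' fitted window, and the new cohort diagonals they introduce) evaluate the
#' spline bases at the unobserved indices — beyond the knot range the bases
#' continue linearly — and multiply by the estimated coefficients.  Interval
#' bounds are `eta_hat +/- z * SE` with the SE from the quadratic form of the
#' prediction row with the Bayesian posterior covariance of the coefficients.
#'
#' @param object An [apc_spline()] fit.
#' @param horizon Number of periods to forecast beyond the fitted window
#'   (default 0).
#' @param level Interval level (default 0.95, i.e. `eta_hat +/- 1.96 SE`).
#' @param ... Unused.
#' @return A tibble of class `apc_pred` with columns `age`, `period`, `a`,
#'   `p`, `c`, `eta`, `se`, `lwr`, `upr`, `forecast`.
#' @export
predict.apc_spline <- function(object, horizon = 0, level = 0.95, ...) {
  cells <- predict_cells(object$design, horizon)
  Xp <- design_rows(object$design, cells)
  eta <- as.numeric(Xp %*% object$theta_hat)
  se <- sqrt(pmax(rowSums((Xp %*% object$Vb) * Xp), 0))
  z <- qnorm(1 - (1 - level) / 2)
  out <- cells
  out$eta <- eta
  out$se <- se
  out$lwr <- eta - z * se
  out$upr <- eta + z * se
  attr(out, "level") <- level
  attr(out, "extrapolation") <- c(
    period = max(0, horizon),
    cohort = max(0, max(cells$c) - object$design$K_fit)
  )
  class(out) <- c("apc_pred", class(out))
  out
}

#' Extract estimated curvature functions
#'
#' @param object A fitted APC model.
#' @param ... Passed to methods.
#' @return A tibble with one row per component index: `component`, `index`,
#'   `value` (age midpoint / period / cohort index), `estimate`, and interval
#'   columns.
#' @export
curvatures <- function(object, ...) UseMethod("curvatures")

#' @rdname curvatures
#' @param level Interval level (default 0.95).
#' @export
curvatures.apc_spline <- function(object, level = 0.95, ...) {
  design <- object$design
  z <- qnorm(1 - (1 - level) / 2)
  g <- design$grid
  labels <- list(
    age = g$age_values,
    period = g$period_start + g$period_width * (seq_len(design$J_fit) - 1),
    cohort = seq_len(design$K_fit)
  )
  purrr::map_dfr(c("age", "period", "cohort"), function(nm) {
    comp <- design$comps[[nm]]
    blk <- design$blocks[[nm]]
    est <- as.numeric(comp$Zt %*% object$theta_hat[blk])
    Vf <- comp$Zt %*% object$Vb[blk, blk, drop = FALSE] %*% t(comp$Zt)
    se <- sqrt(pmax(diag(Vf), 0))
    tibble(
      component = nm, index = seq_len(comp$n), value = labels[[nm]],
      estimate = est, se = se, lwr = est - z * se, upr = est + z * se
    )
  })
}

#' @method tidy apc_spline
#' @export
tidy.apc_spline <- function(x, ...) {
  fixed <- tibble(
    term = c("(Intercept)", paste0("slope_", x$design$slopes)),
    estimate = x$theta_hat[1:3],
    std.error = sqrt(diag(x$Vb)[1:3])
  )
  smooth <- tibble(
    term = paste0("curv_", c("age", "period", "cohort")),
    estimate = NA_real_, std.error = NA_real_,
    edf = as.numeric(x$edf),
    lambda = as.numeric(unlist(x$lambda))
  )
  dplyr::bind_rows(dplyr::mutate(fixed, edf = NA_real_, lambda = NA_real_), smooth)
}

#' @method glance apc_spline
#' @export
glance.apc_spline <- function(x, ...) {
  tibble(
    family = x$family$name,
    basis = x$design$comps$age$kind,
    deviance = x$deviance,
    logLik = x$loglik,
    edf = x$edf_total,
    nobs = sum(!is.na(x$y)),
    criterion = x$criterion,
    criterion_value = x$criterion_value,
    iter = x$iter,
    converged = x$converged
  )
}
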