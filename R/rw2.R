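# Intrinsic random-walk Gaussian Markov random field primitives.

#' Structure matrix of an intrinsic random walk
#'
#' For order 2 (the default), returns `R = t(D) %*% D` with `D` the
#' `(n-2) x n` second-difference operator: a banded matrix with interior
#' stencil `(1, -4, 6, -4, 1)`, corner rows `(1, -2, 1, ...)` and
#' `(-2, 5, -4, 1, ...)`.  Its null space is spanned by constant and linear
#' vectors, so the rank is `n - 2` and the RW2 prior with precision
#' `Q = tau * R` is improper (intrinsic) of rank deficiency 2.  Order 1
#' (first differences, rank deficiency 1) is accepted for completeness.
#'
#' @param n Field length (`n >= 3` for order 2, `n >= 2` for order 1).
#' @param order Random-walk order, 1 or 2 (default 2).
#' @return A sparse symmetric `n x n` matrix (class from the Matrix package).
#' @examples
#' rw2_structure(5)[3, ] # 1 -4 6 -4 1
#' @export
rw2_structure <- function(n, order = 2) {
  if (!order %in% c(1, 2)) abort("`order` must be 1 or 2.")
  if (n < order + 1) {
    abort(sprintf("Field length n = %d too short: order-%d differences are undefined.", n, order))
  }
  stencil <- if (order == 1) c(-1, 1) else c(1, -2, 1)
  nd <- n - order
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(nd), order + 1),
    j = as.vector(outer(seq_len(nd), 0:order, `+`)),
    x = rep(stencil, each = nd),
    dims = c(nd, n)
  )
  Matrix::forceSymmetric(Matrix::crossprod(D))
}

#' Rate of the penalised complexity prior on a random-walk precision
#'
#' The PC prior for the precision `tau` of an intrinsic random walk is an
#' exponential distribution on the standard deviation `sigma = tau^(-1/2)`
#' with rate `kappa`, calibrated through the tail contrast
#' `P(sigma > U) = alpha`, giving `kappa = -log(alpha) / U`.
#'
#' @param u Standard-deviation bound `U > 0`.
#' @param alpha Tail probability in (0, 1).
#' @return The exponential rate `kappa`.
#' @examples
#' pc_prior_rate(1, 0.01) # 4.60517...
#' @export
pc_prior_rate <- function(u, alpha) {
  if (u <= 0) abort("`u` must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1).")
  -log(alpha) / u
}

# log PC-prior density of theta = log(tau): transform sigma ~ Exp(kappa)
# through sigma = exp(-theta / 2).
pc_prior_log_density <- function(theta, kappa) {
  sigma <- exp(-theta / 2)
  log(kappa) - kappa * sigma + log(sigma / 2)
}

#' Log-density of the intrinsic RW2 prior (up to an additive constant)
#'
#' `((n - 2)/2) * log(tau) - (tau/2) * sum of squared second differences`,
#' equal to `((n - 2)/2) * log(tau) - 0.5 * t(f) %*% (tau * R) %*% f` with
#' `R` from [rw2_structure()].  The normalising power of `tau` uses the rank
#' `n - 2` of the intrinsic precision.
#'
#' @param f Field values (length `n >= 3`).
#' @param tau Precision (`> 0`).
#' @return The log-density up to a constant not involving `f` or `tau`.
#' @export
log_prior_rw2 <- function(f, tau) {
  n <- length(f)
  if (n < 3) abort("RW2 log-density needs at least 3 field values.")
  if (tau <= 0) abort("`tau` must be positive.")
  d2 <- diff(f, differences = 2)
  (n - 2) / 2 * log(tau) - tau / 2 * sum(d2^2)
}

#' Forecast distribution of a pure RW2 field
#'
#' Conditional on observed values `f[1..n]`, the RW2 law extends the field by
#' `f[n+t] = 2 f[n+t-1] - f[n+t-2] + e_t`, `e_t ~ N(0, 1/tau)`.  The
#' conditional mean is the linear continuation `(1 + t) f[n] - t f[n-1]` and
#' the conditional variance grows cubically, `t (t + 1) (2 t + 1) / (6 tau)`.
#' Computed here by Gaussian conditioning on the joint structure matrix: the
#' future block of `tau * R` is proper, so
#' `mean = -Q_BB^{-1} Q_BA f` and `cov = Q_BB^{-1}`.
#'
#' @param f Observed field values (length `n >= 2`).
#' @param tau Precision of the second-difference increments.
#' @param horizon Number of future nodes `t >= 1`.
#' @return A tibble with columns `step`, `mean`, `var`.
#' @export
rw2_forecast <- function(f, tau, horizon) {
  n <- length(f)
  if (n < 2) abort("Need at least the last two field values to forecast a RW2.")
  if (horizon < 1) abort("`horizon` must be at least 1.")
  R <- as.matrix(rw2_structure(n + horizon))
  fut <- seq.int(n + 1, n + horizon)
  Q_BB <- tau * R[fut, fut, drop = FALSE]
  Q_BA <- tau * R[fut, seq_len(n), drop = FALSE]
  m <- -solve(Q_BB, Q_BA %*% f)
  V <- solve(Q_BB)
  tibble(step = seq_len(horizon), mean = as.numeric(m), var = diag(V))
}
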