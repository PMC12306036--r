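# Spline bases for curvature components: cubic regression splines (CRS,
# natural cubic in the value-at-knot "cardinal" parameterisation) and cubic
# B-splines, with exact integrated-squared-second-derivative penalties.

#' Equally spaced knots over the range of a covariate
#'
#' @param values Ordered numeric values the basis will be evaluated at.
#' @param n_knots Number of knots (at least 4 for a cubic basis).
#' @return Numeric vector of `n_knots` equally spaced knots spanning
#'   `range(values)` inclusive.
#' @export
make_knots <- function(values, n_knots) {
  if (n_knots < 4) abort("Cubic bases need at least 4 knots.")
  ud <- unique(values)
  if (length(ud) < 2) abort("`values` must span a nondegenerate range.")
  if (n_knots > length(ud)) {
    abort(sprintf(
      "%d knots exceed the %d distinct values: the unpenalised basis would be rank deficient.",
      n_knots, length(ud)
    ))
  }
  seq(min(values), max(values), length.out = n_knots)
}

# CRS machinery (natural cubic spline interpolating values at the knots).
# With spacings h_j, D maps knot values to scaled second differences and the
# tridiagonal B maps interior second derivatives m to them: B m = D gamma.
# The penalty is exact: int f'' ^2 = m' B m = gamma' D' B^{-1} D gamma.
crs_matrices <- function(knots) {
  T_ <- length(knots)
  h <- diff(knots)
  Dm <- matrix(0, T_ - 2, T_)
  Bm <- matrix(0, T_ - 2, T_ - 2)
  for (j in seq_len(T_ - 2)) {
    Dm[j, j] <- 1 / h[j]
    Dm[j, j + 1] <- -1 / h[j] - 1 / h[j + 1]
    Dm[j, j + 2] <- 1 / h[j + 1]
    Bm[j, j] <- (h[j] + h[j + 1]) / 3
    if (j < T_ - 2) {
      Bm[j, j + 1] <- h[j + 1] / 6
      Bm[j + 1, j] <- h[j + 1] / 6
    }
  }
  # F maps knot values to second derivatives at all knots (natural: m1 = mT = 0)
  Fm <- rbind(0, solve(Bm, Dm), 0)
  list(h = h, D = Dm, B = Bm, F = Fm, S = crossprod(Dm, solve(Bm, Dm)))
}

# Evaluate the CRS cardinal basis at x; outside the knot range the natural
# spline continues linearly (zero second derivative beyond the end knots).
crs_eval <- function(x, knots, Fm) {
  T_ <- length(knots)
  n <- length(x)
  Z <- matrix(0, n, T_)
  lo <- knots[1]; hi <- knots[T_]
  xc <- pmin(pmax(x, lo), hi)
  j <- pmin(pmax(findInterval(xc, knots), 1L), T_ - 1L)
  h <- knots[j + 1] - knots[j]
  dl <- knots[j + 1] - xc     # distance to upper knot
  du <- xc - knots[j]         # distance to lower knot
  for (i in seq_len(n)) {
    row <- numeric(T_)
    row[j[i]] <- dl[i] / h[i]
    row[j[i] + 1] <- du[i] / h[i]
    cm_lo <- dl[i]^3 / (6 * h[i]) - h[i] * dl[i] / 6
    cm_hi <- du[i]^3 / (6 * h[i]) - h[i] * du[i] / 6
    row <- row + cm_lo * Fm[j[i], ] + cm_hi * Fm[j[i] + 1, ]
    if (x[i] < lo || x[i] > hi) {
      # first-derivative row at the clamped boundary point
      drow <- -1 / h[i] * replace(numeric(T_), j[i], 1) +
        1 / h[i] * replace(numeric(T_), j[i] + 1, 1) +
        (-3 * dl[i]^2 / (6 * h[i]) + h[i] / 6) * Fm[j[i], ] +
        (3 * du[i]^2 / (6 * h[i]) - h[i] / 6) * Fm[j[i] + 1, ]
      row <- row + (x[i] - xc[i]) * drow
    }
    Z[i, ] <- row
  }
  Z
}

# Cubic B-spline design with linear (first-order Taylor) extension beyond the
# boundary knots, so forecasting evaluates the basis past the data range.
bs_eval <- function(x, knots, deriv = 0L) {
  aug <- c(rep(knots[1], 3), knots, rep(knots[length(knots)], 3))
  lo <- knots[1]; hi <- knots[length(knots)]
  inside <- x >= lo & x <= hi
  n_basis <- length(knots) + 2L
  Z <- matrix(0, length(x), n_basis)
  if (any(inside)) {
    Z[inside, ] <- splines::splineDesign(aug, x[inside], ord = 4L,
                                         derivs = rep(deriv, sum(inside)))
  }
  if (any(!inside)) {
    xb <- ifelse(x[!inside] < lo, lo, hi)
    if (deriv == 0L) {
      Z0 <- splines::splineDesign(aug, xb, ord = 4L)
      Z1 <- splines::splineDesign(aug, xb, ord = 4L, derivs = rep(1L, length(xb)))
      Z[!inside, ] <- Z0 + (x[!inside] - xb) * Z1
    } else if (deriv == 1L) {
      Z[!inside, ] <- splines::splineDesign(aug, xb, ord = 4L,
                                            derivs = rep(1L, length(xb)))
    } # second derivative is zero under the linear extension
  }
  Z
}

# Exact penalty for the cubic B-spline basis: second derivatives are piecewise
# linear, so Simpson's rule on each inter-knot interval integrates the
# product of two of them exactly.
bs_penalty <- function(knots) {
  mids <- (head(knots, -1) + tail(knots, -1)) / 2
  G_lo <- bs_eval(head(knots, -1), knots, deriv = 2L)
  G_mid <- bs_eval(mids, knots, deriv = 2L)
  G_hi <- bs_eval(tail(knots, -1), knots, deriv = 2L)
  h <- diff(knots)
  S <- matrix(0, ncol(G_lo), ncol(G_lo))
  for (j in seq_along(h)) {
    S <- S + h[j] / 6 * (
      tcrossprod(G_lo[j, ]) + 4 * tcrossprod(G_mid[j, ]) + tcrossprod(G_hi[j, ])
    )
  }
  (S + t(S)) / 2
}

#' Build a spline curvature basis with its second-derivative penalty
#'
#' Evaluates a cubic spline basis at `x` and computes the penalty matrix
#' `S[s, t] = integral of g_s''(x) g_t''(x) dx` exactly by piecewise-
#' polynomial integration.  `"cr"` is the natural-cubic cardinal basis (one
#' basis function per knot, value-at-knot parameterisation; g_t(k_s) is 1 if
#' s = t and 0 otherwise); `"bs"` is the cubic B-spline basis (rows sum to 1
#' inside the knot range).  Both reproduce linear functions exactly, so the
#' penalty null space has dimension 2.  Evaluation beyond the knot range
#' continues linearly, which is how forecasts extrapolate.
#'
#' @param kind `"cr"` or `"bs"`.
#' @param x Evaluation points.
#' @param knots Ordered knots from [make_knots()] (at least 4).
#' @return A list with `kind`, `knots`, the `length(x) x T` basis matrix `Z`,
#'   and the `T x T` penalty `S`.
#' @export
build_basis <- function(kind = c("cr", "bs"), x, knots) {
  kind <- match.arg(kind)
  if (length(knots) < 4) abort("Cubic bases need at least 4 knots.")
  if (is.unsorted(knots, strictly = TRUE)) abort("Knots must be strictly increasing.")
  if (kind == "cr") {
    mats <- crs_matrices(knots)
    list(kind = "cr", knots = knots, F = mats$F,
         Z = crs_eval(x, knots, mats$F), S = mats$S)
  } else {
    list(kind = "bs", knots = knots, Z = bs_eval(x, knots), S = bs_penalty(knots))
  }
}

# Re-evaluate a fitted component's (unreduced) basis at new points.
eval_basis <- function(comp, x) {
  if (comp$kind == "cr") {
    crs_eval(x, comp$knots, crs_matrices(comp$knots)$F)
  } else {
    bs_eval(x, comp$knots)
  }
}
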