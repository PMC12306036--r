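# Independent oracles and fixture builders used across the suite.

# RW2 structure matrix built directly from the printed stencil pattern
# (corner rows (1,-2,1,...), (-2,5,-4,1,...), interior (1,-4,6,-4,1)),
# independent of the difference-operator construction in the package.
oracle_structure <- function(n) {
  R <- matrix(0, n, n)
  put <- function(i, vals, j0) {
    jj <- j0 + seq_along(vals) - 1
    keep <- jj >= 1 & jj <= n
    R[i, jj[keep]] <<- vals[keep]
  }
  for (i in seq_len(n)) {
    if (i == 1) put(i, c(1, -2, 1), 1)
    else if (i == 2) put(i, c(-2, 5, -4, 1), 1)
    else if (i == n - 1) put(i, c(1, -4, 5, -2), n - 3)
    else if (i == n) put(i, c(1, -2, 1), n - 2)
    else put(i, c(1, -4, 6, -4, 1), i - 2)
  }
  if (n == 3) { # stencils overlap for the smallest field
    R <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  }
  if (n == 4) {
    R <- matrix(c(1, -2, 1, 0, -2, 5, -4, 1, 1, -4, 5, -2, 0, 1, -2, 1), 4, 4)
  }
  R
}

# empirical quantile implemented from the type-7 definition, independent of
# stats::quantile internals
manual_q <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# numerical integrated squared second derivative of a basis expansion,
# by central differences on a fine grid
num_penalty <- function(kind, knots, gamma, lo = min(knots), hi = max(knots)) {
  h <- (hi - lo) / 4000
  x <- seq(lo, hi, by = h)
  f <- as.numeric(build_basis(kind, x, knots)$Z %*% gamma)
  d2 <- diff(f, differences = 2) / h^2
  mid <- d2 # second derivative at interior points
  sum(mid^2) * h
}

# an exactly additive APC surface on a grid, with constrained curvatures
additive_surface <- function(grid, b0 = -7, b1 = 0.1, b2 = -0.05,
                             amp = c(0.3, 0.2, 0.25)) {
  cells <- as_tibble(grid)
  proj <- function(v) {
    t_ <- seq_along(v)
    A <- cbind(1, t_)
    as.numeric(v - A %*% solve(crossprod(A), crossprod(A, v)))
  }
  fA <- amp[1] * proj(sin(seq_len(grid$I)))
  fP <- amp[2] * proj(cos(seq_len(grid$J) / 2))
  fC <- amp[3] * proj(sin(seq_len(grid$K) / 3))
  eta <- b0 + b1 * (cells$a - (grid$I + 1) / 2) +
    b2 * (cells$p - (grid$J + 1) / 2) +
    fA[cells$a] + fP[cells$p] + fC[cells$c]
  list(cells = cells, eta = eta, fA = fA, fP = fP, fC = fC, b0 = b0)
}

# deterministic small Poisson dataset on a given grid
tiny_poisson <- function(grid, seed = 1, pop = 1e5) {
  surf <- additive_surface(grid)
  set.seed(seed)
  data.frame(
    age = surf$cells$age, period = surf$cells$period,
    deaths = rpois(nrow(surf$cells), pop * exp(surf$eta)),
    population = pop
  )
}
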