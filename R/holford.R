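# Holford-style identifiable APC design: intercept, two slopes, and three
# curvature components each constrained to zero sum and zero linear trend.

# Orthonormal basis of the orthogonal complement of span{1, t} on 1..n,
# via QR of the 2 x n constraint matrix.
constraint_nullspace <- function(n) {
  A <- rbind(rep(1, n), seq_len(n))
  qr.Q(qr(t(A)), complete = TRUE)[, 3:n, drop = FALSE]
}

component_spec <- function(kind = "identity", n_knots = NULL,
                           penalty = c("deriv2", "diff2")) {
  penalty <- match.arg(penalty)
  list(kind = kind, n_knots = n_knots, penalty = penalty)
}

# Build one curvature component on indices 1..n: basis Z (n x T), penalty S,
# and the constraint-reduced forms Zt (n x (T-2)), St after absorbing the
# zero-sum and zero-linear-trend constraints by null-space reparameterisation.
build_component <- function(n, spec) {
  x <- seq_len(n)
  if (spec$kind == "identity") {
    # saturated basis: one coefficient per index, second-difference penalty
    basis <- list(kind = "identity", knots = x,
                  Z = diag(n), S = as.matrix(rw2_structure(n)))
  } else {
    kn <- make_knots(x, spec$n_knots)
    basis <- build_basis(spec$kind, x, kn)
    if (spec$penalty == "diff2") {
      D <- diff(diag(ncol(basis$Z)), differences = 2)
      basis$S <- crossprod(D)
    }
  }
  C <- rbind(rep(1, n), x) %*% basis$Z
  Ng <- qr.Q(qr(t(C)), complete = TRUE)[, 3:ncol(basis$Z), drop = FALSE]
  list(
    n = n, kind = basis$kind, knots = basis$knots, spec = spec,
    Z = basis$Z, S = basis$S, Ngamma = Ng,
    Zt = basis$Z %*% Ng, St = crossprod(Ng, basis$S %*% Ng)
  )
}

# Evaluate the reduced curvature basis at (possibly out-of-range) indices.
component_rows <- function(comp, x) {
  if (comp$kind == "identity") {
    if (any(x < 1 | x > comp$n)) {
      abort("Identity (saturated) bases cannot be evaluated off the fitted index set.")
    }
    comp$Zt[x, , drop = FALSE]
  } else {
    eval_basis(comp, x) %*% comp$Ngamma
  }
}

#' Identifiable (Holford) APC design
#'
#' Assembles the design of the identifiable APC reparameterisation: an
#' intercept, slopes for two of the three time scales (the third slope is
#' dropped; which one is arbitrary and does not affect fitted or forecast
#' linear predictors), and three curvature components, each constrained to
#' have zero sum and zero linear trend over its own index set.  Constraints
#' are absorbed by reparameterising each component basis onto the null space
#' of its 2-row constraint matrix, so the assembled design has full column
#' rank `I + J + K - 3` when each curvature is saturated (one basis function
#' per index).
#'
#' @param grid An [apc_grid()] (possibly extended by [extend_grid()]; the
#'   design is built on the estimation part, `J - horizon` periods).
#' @param drop_slope Which slope to omit: `"cohort"` (default), `"age"`, or
#'   `"period"`.
#' @param bases A list with entries `age`, `period`, `cohort`, each created
#'   by `component_spec()`-style lists `list(kind =, n_knots =, penalty =)`
#'   where `kind` is `"identity"` (saturated, one coefficient per index),
#'   `"cr"` (cubic regression spline) or `"bs"` (cubic B-spline).  Default:
#'   saturated components.
#' @return An object of class `apc_design` with the model matrix `X` over the
#'   estimation cells, per-component reduced bases and penalties, and column
#'   block bookkeeping.
#' @examples
#' g <- apc_grid(0, 1, 3, 0, 1, 3)
#' d <- apc_design(g)
#' qr(d$X)$rank # I + J + K - 3 = 8
#' @export
apc_design <- function(grid, drop_slope = c("cohort", "age", "period"),
                       bases = NULL) {
  stopifnot(inherits(grid, "apc_grid"))
  drop_slope <- match.arg(drop_slope)
  J_fit <- grid$J - grid$horizon
  K_fit <- grid$M * (grid$I - 1L) + J_fit
  if (is.null(bases)) bases <- list()
  defaults <- list(
    age = component_spec("identity"),
    period = component_spec("identity"),
    cohort = component_spec("identity")
  )
  bases <- utils::modifyList(defaults, bases)
  comps <- list(
    age = build_component(grid$I, bases$age),
    period = build_component(J_fit, bases$period),
    cohort = build_component(K_fit, bases$cohort)
  )
  slopes <- setdiff(c("age", "period", "cohort"), drop_slope)
  centres <- c(
    age = (grid$I + 1) / 2, period = (J_fit + 1) / 2, cohort = (K_fit + 1) / 2
  )
  design <- structure(
    list(
      grid = grid, J_fit = J_fit, K_fit = K_fit,
      drop_slope = drop_slope, slopes = slopes, centres = centres,
      comps = comps
    ),
    class = "apc_design"
  )
  cells <- design_cells(design, forecast = FALSE)
  design$cells <- cells
  design$X <- design_rows(design, cells)
  ncomp <- vapply(comps, function(cc) ncol(cc$Zt), 1L)
  ends <- 3L + cumsum(ncomp)
  starts <- c(4L, head(ends, -1) + 1L)
  design$blocks <- list(
    fixed = 1:3,
    age = seq.int(starts[1], ends[1]),
    period = seq.int(starts[2], ends[2]),
    cohort = seq.int(starts[3], ends[3])
  )
  design
}

# Cell table for the estimation window (forecast = FALSE) or the full
# extended grid (forecast = TRUE).
design_cells <- function(design, forecast = FALSE) {
  g <- design$grid
  Jmax <- if (forecast) g$J else design$J_fit
  cells <- expand.grid(p = seq_len(Jmax), a = seq_len(g$I))
  tibble(
    a = as.integer(cells$a), p = as.integer(cells$p),
    c = cohort_index(g, cells$a, cells$p),
    age = g$age_values[cells$a],
    period = g$period_start + g$period_width * (cells$p - 1),
    forecast = cells$p > design$J_fit
  )
}

# Model-matrix rows for arbitrary cells (p, c may exceed the fitted ranges;
# spline bases extrapolate, slope columns keep the estimation centring).
design_rows <- function(design, cells) {
  idx <- list(age = cells$a, period = cells$p, cohort = cells$c)
  slope_cols <- vapply(
    design$slopes,
    function(s) idx[[s]] - design$centres[[s]],
    numeric(nrow(cells))
  )
  X <- cbind(
    1, slope_cols,
    component_rows(design$comps$age, cells$a),
    component_rows(design$comps$period, cells$p),
    component_rows(design$comps$cohort, cells$c)
  )
  colnames(X) <- NULL
  X
}

# Block-diagonal penalty matrix for coefficient vector ordered as the design
# columns; fixed effects unpenalised.
design_penalty <- function(design, lambda) {
  q <- 3L + sum(vapply(design$comps, function(cc) ncol(cc$Zt), 1L))
  P <- matrix(0, q, q)
  for (nm in c("age", "period", "cohort")) {
    b <- design$blocks[[nm]]
    P[b, b] <- lambda[[nm]] * design$comps[[nm]]$St
  }
  P
}

# Map coefficient vector to per-component curvature values f_T(t).
design_curvatures <- function(design, theta) {
  lapply(
    stats::setNames(c("age", "period", "cohort"), c("age", "period", "cohort")),
    function(nm) as.numeric(design$comps[[nm]]$Zt %*% theta[design$blocks[[nm]]])
  )
}

#' Decompose a linear-predictor surface into identifiable APC components
#'
#' Projects a surface `eta` over the estimation cells of a grid onto the
#' identifiable APC model space (intercept + two slopes + three constrained
#' curvatures, saturated representation) by least squares.  When `eta` is
#' exactly additive in age, period and cohort the decomposition is exact;
#' otherwise the residual root-mean-square reports the non-APC remainder.
#'
#' @details On unequal-interval grids (`M > 1`) the saturated APC design has
#'   additional exact collinearities beyond the classical one: functions with
#'   period-`M` cycles in cohort alias exactly with the corresponding cycles
#'   in period (`c mod M = p mod M`), the source of the artificial cyclic
#'   patterns that motivate smoothing.  The decomposition therefore uses the
#'   minimum-norm least-squares solution (SVD pseudo-inverse), which is
#'   unique and allocates any aliased content symmetrically; for smooth
#'   surfaces the aliased content is negligible.
#'
#' @param grid An [apc_grid()].
#' @param eta Numeric vector over the grid cells in period-within-age order.
#' @param drop_slope Slope to omit, as in [apc_design()].
#' @return A list with `beta0`, `slopes` (named length-2), `curvatures`
#'   (list of numeric vectors for age, period, cohort), `fitted`, and
#'   `residual_rms`.
#' @export
decompose_eta <- function(grid, eta, drop_slope = "cohort") {
  design <- apc_design(grid, drop_slope = drop_slope)
  if (length(eta) != nrow(design$X)) {
    abort("`eta` must have one value per estimation cell of the grid.")
  }
  sv <- svd(design$X)
  pos <- sv$d > 1e-10 * sv$d[1]
  theta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], eta)) / sv$d[pos])
  theta <- as.numeric(theta)
  fitted <- as.numeric(design$X %*% theta)
  list(
    beta0 = theta[1],
    slopes = stats::setNames(theta[2:3], design$slopes),
    curvatures = design_curvatures(design, theta),
    fitted = fitted,
    residual_rms = sqrt(mean((eta - fitted)^2))
  )
}
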