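#' Build an age-period-cohort grid
#'
#' An APC grid records the index bookkeeping for count data cross-classified
#' by age group and period, including the cohort (birth-time) diagonal.  Ages
#' may be aggregated into wider intervals than periods; the integer ratio
#' `M = age_width / period_width` enters the cohort index
#' `c = M * (I - a) + p`, which runs from 1 (oldest age, first period) to
#' `K = M * (I - 1) + J` (youngest age, last period).
#'
#' @param age_start Lower edge of the first age interval (years).
#' @param age_width Width of each age interval (years).
#' @param n_age Number of age groups `I` (at least 2).
#' @param period_start First period (e.g. calendar year).
#' @param period_width Width of each period interval (years), default 1.
#' @param n_period Number of periods `J` (at least 2).
#'
#' @return An object of class `apc_grid`: a list with elements `I`, `J`, `M`,
#'   `K`, `age_values` (interval midpoints), `period_values`, and the interval
#'   metadata needed to serialise the grid.
#' @examples
#' g <- apc_grid(25, 5, 12, 2006, 1, 16)
#' g$K # 71 cohorts
#' @export
apc_grid <- function(age_start, age_width, n_age,
                     period_start, period_width = 1, n_period) {
  if (n_age < 2) abort("`n_age` must be at least 2.")
  if (n_period < 2) abort("`n_period` must be at least 2.")
  if (age_width <= 0 || period_width <= 0) {
    abort("Interval widths must be positive.")
  }
  ratio <- age_width / period_width
  if (abs(ratio - round(ratio)) > 1e-8) {
    abort(sprintf(
      "Age interval width (%g) must be an integer multiple of the period width (%g).",
      age_width, period_width
    ))
  }
  M <- as.integer(round(ratio))
  I <- as.integer(n_age)
  J <- as.integer(n_period)
  structure(
    list(
      I = I, J = J, M = M, K = as.integer(M * (I - 1L) + J),
      age_start = age_start, age_width = age_width,
      period_start = period_start, period_width = period_width,
      age_values = age_start + age_width * (seq_len(I) - 0.5),
      period_values = period_start + period_width * (seq_len(J) - 1),
      horizon = 0L, new_cohorts = integer(0)
    ),
    class = "apc_grid"
  )
}

#' @export
print.apc_grid <- function(x, ...) {
  cat(sprintf(
    "<apc_grid> I = %d age groups, J = %d periods, M = %d, K = %d cohorts\n",
    x$I, x$J, x$M, x$K
  ))
  cat(sprintf(
    "  ages: midpoints %g ... %g (width %g); periods: %g ... %g (width %g)\n",
    x$age_values[1], x$age_values[x$I], x$age_width,
    x$period_values[1], x$period_values[x$J], x$period_width
  ))
  if (x$horizon > 0) {
    cat(sprintf(
      "  extended by %d forecast period(s); new cohorts: %s\n",
      x$horizon, paste(x$new_cohorts, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Cohort index for an (age, period) cell
#'
#' Computes `c = M * (I - a) + p`.  The period index may exceed the grid's `J`
#' when indexing forecast cells.
#'
#' @param grid An [apc_grid()].
#' @param a Age-group index (1 = youngest group), in `1..I`.
#' @param p Period index (1 = first period); values above `J` address
#'   forecast periods.
#' @return Integer cohort index (vectorised over `a`, `p`).
#' @export
cohort_index <- function(grid, a, p) {
  stopifnot(inherits(grid, "apc_grid"))
  if (any(a < 1 | a > grid$I)) {
    abort(sprintf("Age index out of range 1..%d.", grid$I))
  }
  if (any(p < 1)) abort("Period index must be at least 1.")
  as.integer(grid$M * (grid$I - a) + p)
}

#' Extend a grid by forecast periods
#'
#' Adds `t` periods to the grid.  The extended grid has `J' = J + t` periods
#' and `K' = M*(I-1) + J + t` cohorts; existing cells keep their (a, p, c)
#' triples.  Cohort indices above the original `K` are genuinely new and
#' require forecasting, while cohorts already observed merely repeat over the
#' added period columns.
#'
#' @param grid An [apc_grid()].
#' @param t Forecast horizon in periods (>= 1).
#' @return An `apc_grid` with `horizon` set and `new_cohorts` listing the
#'   cohort indices introduced by the extension.
#' @export
extend_grid <- function(grid, t) {
  stopifnot(inherits(grid, "apc_grid"))
  if (t < 1) abort("Forecast horizon `t` must be at least 1.")
  t <- as.integer(t)
  out <- grid
  out$J <- grid$J + t
  out$K <- as.integer(grid$M * (grid$I - 1L) + grid$J + t)
  out$period_values <- grid$period_start +
    grid$period_width * (seq_len(out$J) - 1)
  out$horizon <- grid$horizon + t
  out$new_cohorts <- seq.int(grid$K + 1L, out$K)
  out
}

#' Enumerate the cells of a grid as a tibble
#'
#' @param x An [apc_grid()].
#' @param ... Unused.
#' @return A tibble with one row per (age, period) cell: indices `a`, `p`,
#'   `c`, labels `age` (midpoint), `period`, and `forecast` flagging cells in
#'   periods added by [extend_grid()].
#' @method as_tibble apc_grid
#' @export
as_tibble.apc_grid <- function(x, ...) {
  cells <- expand.grid(p = seq_len(x$J), a = seq_len(x$I))
  tibble(
    a = as.integer(cells$a),
    p = as.integer(cells$p),
    c = cohort_index(x, cells$a, cells$p),
    age = x$age_values[cells$a],
    period = x$period_values[cells$p],
    forecast = cells$p > (x$J - x$horizon)
  )
}

#' Validate an APC count table and attach its grid
#'
#' Checks that a data frame of per-cell records (columns `age`, `period`,
#' `deaths`, `population`) forms a complete rectangular APC grid, and attaches
#' an [apc_grid()] describing it.  `age` holds interval midpoints; the age
#' interval width is inferred from their spacing (or given explicitly).
#' Missing `deaths` are allowed — such cells carry no likelihood contribution
#' but their linear predictor is still predicted.
#'
#' @param data A data frame with columns `age`, `period`, `deaths`,
#'   `population`.
#' @param age_width Age interval width in years; default inferred from the
#'   spacing of `age`.
#' @param check_counts Require `deaths` to be non-negative integers (default
#'   `TRUE`; the gaussian family relaxes this to any numeric response).
#' @return A tibble of the cells (ordered by period within age) with class
#'   `apc_df` and the grid in `attr(, "grid")`.
#' @export
as_apc_data <- function(data, age_width = NULL, check_counts = TRUE) {
  need <- c("age", "period", "deaths", "population")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing columns: ", paste(miss, collapse = ", "), "."))
  }
  ages <- sort(unique(data$age))
  periods <- sort(unique(data$period))
  if (length(ages) < 2 || length(periods) < 2) {
    abort("Need at least two distinct ages and periods.")
  }
  dage <- diff(ages)
  dper <- diff(periods)
  if (max(abs(dage - dage[1])) > 1e-8 || max(abs(dper - dper[1])) > 1e-8) {
    abort("Ages and periods must be equally spaced.")
  }
  age_width <- age_width %||% dage[1]
  if (nrow(data) != length(ages) * length(periods)) {
    abort("Data must contain every age x period combination exactly once.")
  }
  if (any(data$population <= 0)) abort("`population` must be positive.")
  obs <- data$deaths[!is.na(data$deaths)]
  if (check_counts && (any(obs < 0) || any(abs(obs - round(obs)) > 1e-8))) {
    abort("`deaths` must be non-negative integers (or NA).")
  }
  grid <- apc_grid(
    age_start = ages[1] - age_width / 2, age_width = age_width,
    n_age = length(ages),
    period_start = periods[1], period_width = dper[1],
    n_period = length(periods)
  )
  out <- as_tibble(data[need])
  out <- out[order(match(out$age, ages), match(out$period, periods)), ]
  out$a <- match(out$age, ages)
  out$p <- match(out$period, periods)
  out$c <- cohort_index(grid, out$a, out$p)
  attr(out, "grid") <- grid
  class(out) <- c("apc_df", class(out))
  out
}

#' @export
print.apc_df <- function(x, ...) {
  g <- attr(x, "grid")
  if (!is.null(g)) print(g)
  NextMethod()
}

apc_grid_of <- function(data) {
  g <- attr(data, "grid")
  if (is.null(g)) g <- attr(as_apc_data(data), "grid")
  g
}

#' Empirical log-rates with the 1/2 continuity correction
#'
#' Returns `log((deaths + 0.5) / population)` (by default), the display/
#' scoring convention for observed data: an extra half event guards against
#' taking the log of zero.  The correction is never applied in model fitting.
#'
#' @param deaths Event counts.
#' @param population Population at risk.
#' @param correction Half-event correction to add (default 0.5; use 0 for the
#'   uncorrected convention).
#' @return Numeric vector of empirical log-rates.
#' @export
empirical_log_rate <- function(deaths, population, correction = 0.5) {
  log((deaths + correction) / population)
}
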