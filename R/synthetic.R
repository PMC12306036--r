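# Synthetic APC mortality-count generator: single-year ages x periods with a
# fixed population at risk, smooth age/period/cohort effects (linear trends
# plus curvature), Poisson (or negative-binomial) counts, then aggregation of
# ages into wider bands modelled at their midpoints.

project_curvature <- function(v) {
  n <- length(v)
  t_ <- seq_len(n)
  A <- cbind(1, t_)
  as.numeric(v - A %*% solve(crossprod(A), crossprod(A, v)))
}

#' Configuration of the synthetic APC simulation
#'
#' Defaults emulate a rare-cause mortality surface: single-year ages 10-84
#' and periods 2000-2020, a fixed population at risk of 750,000 per
#' single-year cell, smooth curvature shapes on each time scale (a Gaussian
#' bump in age, a sine in period, a damped cosine in cohort) with linear
#' trends, a global shift placing the aggregated cells at a few tens of
#' events on average, aggregation into five-year age bands modelled at
#' midpoints 12.5, ..., 82.5, an estimation window of 2000-2017 and a
#' three-period forecast window 2018-2020.
#'
#' @param ages Integer vector of single-year ages (default `10:84`).
#' @param periods Integer vector of periods (default `2000:2020`).
#' @param population Population at risk per single-year cell (default
#'   750000).
#' @param agg_width Age-aggregation width in years (default 5; must divide
#'   the number of ages).
#' @param fit_end Last period of the estimation window (default 2017).
#' @param shift Global intercept of the log-rate surface (default -11.3,
#'   placing aggregated cells near 46 events on average).
#' @param slope_age,slope_period Linear trends per single-year index.
#' @param curv_fun List of three raw shape functions of the (1-based)
#'   single-year index, named `age`, `period`, `cohort`; each is projected
#'   onto the zero-sum / zero-linear-trend space before use.
#' @param curv_scale Named multipliers applied to the projected shapes.
#' @param family `"poisson"` (default) or `"negative_binomial"`.
#' @param nb_dispersion Negative-binomial size parameter (only used for that
#'   family; default 20).
#' @return A list of class `sim_config`, with the projected curvature
#'   vectors stored in `$curv` (satisfying the constraints to 1e-10).
#' @export
sim_config <- function(ages = 10:84, periods = 2000:2020,
                       population = 750000, agg_width = 5,
                       fit_end = 2017, shift = -11.3,
                       slope_age = 0.025, slope_period = 0.008,
                       curv_fun = list(
                         age = function(t) exp(-((t - 36) / 14)^2),
                         period = function(t) sin(2 * pi * (t - 1) / 14),
                         cohort = function(t) cos(2 * pi * (t - 1) / 35)
                       ),
                       curv_scale = c(age = 0.9, period = 0.25, cohort = 0.3),
                       family = c("poisson", "negative_binomial"),
                       nb_dispersion = 20) {
  family <- match.arg(family)
  n_age <- length(ages)
  n_per <- length(periods)
  if (n_age %% agg_width != 0) {
    abort("The number of single-year ages must be divisible by `agg_width`.")
  }
  if (!fit_end %in% periods) {
    abort("`fit_end` must be one of the simulated periods.")
  }
  n_coh <- (n_age - 1) + n_per
  curv <- list(
    age = curv_scale[["age"]] * project_curvature(curv_fun$age(seq_len(n_age))),
    period = curv_scale[["period"]] *
      project_curvature(curv_fun$period(seq_len(n_per))),
    cohort = curv_scale[["cohort"]] *
      project_curvature(curv_fun$cohort(seq_len(n_coh)))
  )
  for (nm in names(curv)) {
    v <- curv[[nm]]
    t_ <- seq_along(v)
    if (abs(sum(v)) > 1e-8 || abs(sum(t_ * v)) > 1e-8) {
      abort(sprintf("Curvature '%s' fails the constraints after projection.", nm))
    }
  }
  structure(
    list(
      ages = ages, periods = periods, population = population,
      agg_width = agg_width, fit_end = fit_end,
      shift = shift, slope_age = slope_age, slope_period = slope_period,
      curv = curv, family = family, nb_dispersion = nb_dispersion
    ),
    class = "sim_config"
  )
}

#' True linear predictor of the simulation, single-year and aggregated
#'
#' The single-year truth is
#' `eta = shift + slope_age * (a - mean) + slope_period * (p - mean) +
#' f_A(a) + f_P(p) + f_C(c)` on indices; the aggregated truth is the exact
#' log mean rate of each age band,
#' `log(sum(pop * exp(eta)) / sum(pop))`, which is what an APC model of the
#' aggregated counts estimates.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `single` (columns `age`, `period`, `a`, `p`,
#'   `c`, `eta`) and `aggregated` (columns `age` (band midpoint), `period`,
#'   `a`, `p`, `eta_true`).
#' @export
sim_true_eta <- function(config) {
  n_age <- length(config$ages)
  n_per <- length(config$periods)
  cells <- expand.grid(p = seq_len(n_per), a = seq_len(n_age))
  a <- cells$a
  p <- cells$p
  cc <- (n_age - a) + p
  eta <- config$shift +
    config$slope_age * (a - (n_age + 1) / 2) +
    config$slope_period * (p - (n_per + 1) / 2) +
    config$curv$age[a] + config$curv$period[p] + config$curv$cohort[cc]
  single <- tibble(
    age = config$ages[a], period = config$periods[p],
    a = as.integer(a), p = as.integer(p), c = as.integer(cc), eta = eta
  )
  w <- config$agg_width
  aggregated <- single |>
    dplyr::mutate(band = (.data$a - 1) %/% w) |>
    dplyr::group_by(.data$band, .data$period, .data$p) |>
    dplyr::summarise(
      age = min(config$ages) + .data$band[1] * w + w / 2,
      eta_true = log(mean(exp(.data$eta))),
      .groups = "drop"
    ) |>
    dplyr::mutate(a = as.integer(.data$band + 1)) |>
    dplyr::arrange(.data$a, .data$p) |>
    dplyr::select("age", "period", "a", "p", "eta_true")
  list(single = single, aggregated = aggregated)
}

#' Simulate single-year APC counts
#'
#' Draws `deaths ~ Poisson(population * exp(eta))` (or negative binomial
#' with the configured dispersion) for every single-year age x period cell.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A tibble with columns `age`, `period`, `deaths`, `population`.
#' @export
sim_counts <- function(config, seed = 1) {
  truth <- sim_true_eta(config)$single
  rate <- config$population * exp(truth$eta)
  if (any(!is.finite(rate)) || any(rate > 1e12)) {
    bad <- which(!is.finite(rate) | rate > 1e12)[1]
    abort(sprintf(
      "Rate overflow at age %g, period %g.", truth$age[bad], truth$period[bad]
    ))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  deaths <- if (config$family == "poisson") {
    rpois(nrow(truth), rate)
  } else {
    rnbinom(nrow(truth), size = config$nb_dispersion, mu = rate)
  }
  tibble(
    age = truth$age, period = truth$period,
    deaths = deaths, population = config$population
  )
}

#' Aggregate single-year ages into bands modelled at their midpoints
#'
#' Counts and exposures are summed within consecutive `width`-year age bands
#' (summing exposure preserves expected counts); the band is labelled by the
#' midpoint of the covered interval, e.g. ages 10-14 by 12.5.
#'
#' @param data Single-year tibble with columns `age`, `period`, `deaths`,
#'   `population`.
#' @param width Band width in years (default 5).
#' @return An [as_apc_data()] tibble on the aggregated grid (M = width /
#'   period width).
#' @export
aggregate_ages <- function(data, width = 5) {
  ages <- sort(unique(data$age))
  if (length(ages) %% width != 0) {
    abort(sprintf(
      "%d single-year ages do not fill %g-year bands: ragged final band.",
      length(ages), width
    ))
  }
  a0 <- min(ages)
  agg <- data |>
    dplyr::mutate(band = (.data$age - a0) %/% width) |>
    dplyr::group_by(.data$band, .data$period) |>
    dplyr::summarise(
      age = a0 + .data$band[1] * width + width / 2,
      deaths = sum(.data$deaths),
      population = sum(.data$population),
      .groups = "drop"
    ) |>
    dplyr::select("age", "period", "deaths", "population")
  as_apc_data(agg, age_width = width)
}

#' One aggregated synthetic dataset
#'
#' Convenience wrapper: [sim_counts()] then [aggregate_ages()], optionally
#' truncated to the estimation window.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param window `"all"` (default) or `"fit"` (periods up to
#'   `config$fit_end`).
#' @return An `apc_df` tibble on the aggregated modelling grid.
#' @export
sim_apc_data <- function(config, seed = 1, window = c("all", "fit")) {
  window <- match.arg(window)
  d <- aggregate_ages(sim_counts(config, seed), config$agg_width)
  if (window == "fit") {
    d <- as_apc_data(d[d$period <= config$fit_end, ])
  }
  d
}

#' Small deterministic fixture dataset
#'
#' A 5 age-group x 8 period aggregated Poisson dataset (M = 5) generated
#' from a reduced configuration with a fixed seed, for examples and unit
#' tests.
#'
#' @param seed Integer seed (default 42).
#' @return An `apc_df` tibble with 40 cells.
#' @export
sim_fixture <- function(seed = 42) {
  cfg <- sim_config(
    ages = 30:54, periods = 2001:2008, population = 500000,
    agg_width = 5, fit_end = 2008, shift = -10.5,
    curv_scale = c(age = 0.5, period = 0.15, cohort = 0.2)
  )
  sim_apc_data(cfg, seed = seed)
}
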