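# Orchestration: the simulation-study comparison (model roster x replicates
# x estimation/forecasting scores) and the real-data workflow.

#' Model roster for the estimation/forecasting comparison
#'
#' @param spline_bases Spline bases to include (subset of `c("cr", "bs")`).
#' @param knots Knot counts for the spline models (age/period/cohort),
#'   default `c(10, 10, 12)`.
#' @param rw2_u PC-prior standard-deviation bounds `U` for the RW2 models
#'   (default `c(1, 3, 6)`).
#' @param pc_alpha PC-prior tail probability (default 0.01).
#' @return A tibble with one row per model: `model`, `type`, `basis`,
#'   `pc_u`.
#' @export
study_models <- function(spline_bases = c("cr", "bs"),
                         knots = c(age = 10, period = 10, cohort = 12),
                         rw2_u = c(1, 3, 6), pc_alpha = 0.01) {
  rows <- list()
  for (b in spline_bases) {
    rows[[length(rows) + 1]] <- tibble(
      model = paste0("spline_", b), type = "spline", basis = b,
      pc_u = NA_real_
    )
  }
  for (u in rw2_u) {
    rows[[length(rows) + 1]] <- tibble(
      model = paste0("rw2_u", u), type = "rw2", basis = NA_character_,
      pc_u = u
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("The model roster must not be empty.")
  attr(out, "knots") <- knots
  attr(out, "pc_alpha") <- pc_alpha
  out
}

replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 10000 + r) %% .Machine$integer.max)
}

#' Run the simulation-study comparison
#'
#' For each replicate: generate single-year counts from `config`, aggregate
#' ages, fit every roster model on the estimation window (periods up to
#' `config$fit_end`), forecast the held-out periods, and score estimation
#' and forecasting cells separately against the noiseless generator truth
#' (the exact aggregated log-rate surface).  Per-model failures are recorded
#' and the study continues unless more than 20% of fits fail.
#'
#' @param config A [sim_config()].
#' @param models A [study_models()] roster.
#' @param n_rep Number of replicate datasets (default 100).
#' @param seed Global seed; replicate `r` uses `seed * 10000 + r`.
#' @param mcmc Sampler budget for RW2 models:
#'   `list(iter =, burnin =, thin =)`.
#' @param level Interval level for scoring (default 0.95).
#' @param progress Print one line per replicate (default `FALSE`).
#' @return An object of class `apc_study`: `cell_scores` (per cell x model
#'   x replicate), `replicate_scores` (per model x replicate x window means,
#'   the boxplot quantities), `summary` (per model x window grand means),
#'   `failures`, and the inputs.
#' @export
run_simulation_study <- function(config = sim_config(),
                                 models = study_models(),
                                 n_rep = 100, seed = 1,
                                 mcmc = list(iter = 20000, burnin = 5000, thin = 5),
                                 level = 0.95, progress = FALSE) {
  knots <- attr(models, "knots") %||% c(age = 10, period = 10, cohort = 12)
  pc_alpha <- attr(models, "pc_alpha") %||% 0.01
  horizon <- sum(config$periods > config$fit_end)
  truth <- sim_true_eta(config)$aggregated
  fam <- if (config$family == "poisson") "poisson" else "negative_binomial"
  theta <- if (fam == "negative_binomial") config$nb_dispersion else NULL

  all_scores <- list()
  failures <- list()
  for (r in seq_len(n_rep)) {
    rs <- replicate_seed(seed, r)
    data_fit <- sim_apc_data(config, seed = rs, window = "fit")
    for (i in seq_len(nrow(models))) {
      mod <- models[i, ]
      res <- tryCatch({
        pred <- if (mod$type == "spline") {
          fit <- apc_spline(data_fit, basis = mod$basis, knots = knots,
                            family = fam, theta = theta)
          predict(fit, horizon = horizon, level = level)
        } else {
          fit <- apc_rw2(data_fit, horizon = horizon, pc_u = mod$pc_u,
                         pc_alpha = pc_alpha, family = fam, theta = theta,
                         iter = mcmc$iter, burnin = mcmc$burnin,
                         thin = mcmc$thin, seed = rs)
          predict(fit, level = level)
        }
        sc <- score_cells(pred, truth, level = level)
        sc$model <- mod$model
        sc$replicate <- r
        sc
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- tibble(
          replicate = r, model = mod$model, message = conditionMessage(res)
        )
      } else {
        all_scores[[length(all_scores) + 1]] <- res
      }
    }
    n_fits <- r * nrow(models)
    if (length(failures) > 0.2 * n_fits) {
      abort(sprintf(
        "More than 20%% of model fits failed (%d of %d); aborting the study.",
        length(failures), n_fits
      ))
    }
    if (progress) {
      message(sprintf("replicate %d/%d done", r, n_rep))
    }
  }
  cell_scores <- dplyr::bind_rows(all_scores)
  replicate_scores <- cell_scores |>
    dplyr::mutate(window = ifelse(.data$forecast, "forecasting", "estimation")) |>
    dplyr::group_by(.data$model, .data$replicate, .data$window) |>
    dplyr::summarise(
      mae = mean(.data$abs_err), mse = mean(.data$sq_err),
      is = mean(.data$is), width = mean(.data$width),
      coverage = mean(.data$covered), .groups = "drop"
    )
  structure(
    list(
      cell_scores = cell_scores,
      replicate_scores = replicate_scores,
      summary = summarize_scores(cell_scores, by = "model"),
      failures = dplyr::bind_rows(failures),
      config = config, models = models, n_rep = n_rep, seed = seed,
      mcmc = mcmc, level = level
    ),
    class = "apc_study"
  )
}

#' @export
print.apc_study <- function(x, ...) {
  cat(sprintf(
    "<apc_study> %d models x %d replicates (%d fit failures)\n",
    nrow(x$models), x$n_rep, nrow(x$failures)
  ))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Real-data workflow: fit, forecast and score the two headline models
#'
#' Fits the penalised-spline model (on the estimation-window rows only) and
#' the RW2 model (on the full grid with held-out counts treated as
#' unobserved) to an observed APC count table, forecasts the held-out
#' periods, and scores both models against the observed empirical log-rates
#' (with the half-event continuity correction by default; set
#' `correction = 0` for the uncorrected convention — the report records
#' which was used).
#'
#' @param data An APC count table (data frame, `apc_df`, or a path to a CSV
#'   readable by [read_apc()]).
#' @param fit_end Last period of the estimation window.
#' @param basis Spline basis (default `"cr"`).
#' @param knots Spline knot counts (default `c(10, 10, 12)`, reduced to the
#'   index lengths when larger).
#' @param pc_u,pc_alpha RW2 PC-prior contrast (defaults 1, 0.01 for every
#'   field).
#' @param family `"poisson"` (default) or `"negative_binomial"` (set
#'   `theta`) as a sensitivity analysis.
#' @param theta Negative-binomial dispersion when used.
#' @param mcmc Sampler budget for the RW2 model.
#' @param level Interval level (default 0.95).
#' @param correction Half-event correction for the observed log-rates
#'   (default 0.5).
#' @param seed Seed for the RW2 sampler.
#' @return An object of class `apc_real`: `scores` (model x window table of
#'   IS/width/coverage/MAE/MSE), `trajectories` (per-age fitted/forecast
#'   series with intervals for both models plus the observed log-rates),
#'   the two fits, and the truth convention used.
#' @export
run_real_data <- function(data, fit_end, basis = "cr",
                          knots = c(age = 10, period = 10, cohort = 12),
                          pc_u = 1, pc_alpha = 0.01,
                          family = c("poisson", "negative_binomial"),
                          theta = NULL,
                          mcmc = list(iter = 20000, burnin = 5000, thin = 5),
                          level = 0.95, correction = 0.5, seed = 1) {
  family <- match.arg(family)
  if (is.character(data)) data <- read_apc(data)
  data <- as_apc_data(data)
  if (!fit_end %in% data$period) abort("`fit_end` must be an observed period.")
  horizon <- length(unique(data$period[data$period > fit_end]))
  data_fit <- as_apc_data(data[data$period <= fit_end, ])

  truth <- data |>
    dplyr::mutate(
      eta_true = empirical_log_rate(.data$deaths, .data$population, correction)
    ) |>
    dplyr::select("age", "period", "eta_true")
  # re-key truth cells to the estimation grid's (a, p) indexing
  gfit <- attr(data_fit, "grid")
  truth$a <- match(truth$age, gfit$age_values)
  truth$p <- round((truth$period - gfit$period_start) / gfit$period_width) + 1L

  fit_spline <- apc_spline(data_fit, basis = basis, knots = knots,
                           family = family, theta = theta)
  pred_spline <- predict(fit_spline, horizon = horizon, level = level)
  fit_rw2 <- apc_rw2(data_fit, horizon = horizon, pc_u = pc_u,
                     pc_alpha = pc_alpha, family = family, theta = theta,
                     iter = mcmc$iter, burnin = mcmc$burnin, thin = mcmc$thin,
                     seed = seed)
  pred_rw2 <- predict(fit_rw2, level = level)

  sc <- dplyr::bind_rows(
    dplyr::mutate(score_cells(pred_spline, truth, level), model = "spline"),
    dplyr::mutate(score_cells(pred_rw2, truth, level), model = "rw2")
  )
  scores <- summarize_scores(sc, by = "model")
  trajectories <- sc |>
    dplyr::select(dplyr::all_of(c(
      "model", "age", "period", "eta", "lwr", "upr", "forecast", "eta_true"
    )))
  structure(
    list(
      scores = scores, trajectories = trajectories,
      spline = fit_spline, rw2 = fit_rw2,
      fit_end = fit_end, horizon = horizon, level = level,
      truth_convention = sprintf(
        "observed log((deaths + %g) / population)", correction
      )
    ),
    class = "apc_real"
  )
}

#' @export
print.apc_real <- function(x, ...) {
  cat(sprintf(
    "<apc_real> estimation through %s, %d forecast period(s); truth: %s\n",
    x$fit_end, x$horizon, x$truth_convention
  ))
  print(x$scores, n = Inf)
  invisible(x)
}
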