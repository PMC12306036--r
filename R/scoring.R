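# Predictive scores on the linear-predictor (log-rate) scale: MAE, MSE,
# interval score, mean interval width, empirical coverage.

#' Interval score of a central predictive interval
#'
#' For a central `(1 - alpha)` interval `[l, u]` and outcome `eta`,
#' `IS = (u - l) + (2/alpha) (l - eta) 1[eta < l] + (2/alpha) (eta - u) 1[eta > u]`.
#' The score equals the width when the outcome falls inside the interval and
#' grows linearly in the violation distance outside; lower is better.
#'
#' @param lwr,upr Interval bounds (`lwr <= upr`), vectorised.
#' @param eta Outcomes.
#' @param level Interval level (default 0.95, so `alpha = 0.05`).
#' @return Numeric vector of per-cell interval scores.
#' @examples
#' interval_score(0, 1, 0.5) # 1: inside, IS = width
#' interval_score(0, 1, 1.5) # 21: 1 + 40 * 0.5
#' @export
interval_score <- function(lwr, upr, eta, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must lie strictly in (0, 1).")
  if (any(lwr > upr + 1e-12, na.rm = TRUE)) abort("`lwr` must not exceed `upr`.")
  alpha <- 1 - level
  (upr - lwr) +
    2 / alpha * (lwr - eta) * (eta < lwr) +
    2 / alpha * (eta - upr) * (eta > upr)
}

#' Per-cell predictive scores against a truth surface
#'
#' Joins predictions (an `apc_pred` tibble or any data frame with columns
#' `a`, `p`, `eta`, `lwr`, `upr`, `forecast`) with per-cell truth and returns
#' the per-cell absolute error, squared error, interval score, width and
#' coverage indicator.
#'
#' @param predictions Prediction tibble (see above).
#' @param truth Data frame with columns `a`, `p`, `eta_true`, or a numeric
#'   vector aligned with `predictions`.
#' @param level Interval level used for the interval score (default the
#'   predictions' own level attribute, else 0.95).
#' @return The predictions tibble with columns `eta_true`, `abs_err`,
#'   `sq_err`, `is`, `width`, `covered` appended.
#' @export
score_cells <- function(predictions, truth, level = NULL) {
  level <- level %||% attr(predictions, "level") %||% 0.95
  out <- as_tibble(predictions)
  if (is.numeric(truth) && is.null(dim(truth))) {
    if (length(truth) != nrow(out)) {
      abort("`truth` vector must have one value per prediction row.")
    }
    out$eta_true <- truth
  } else {
    need <- c("a", "p", "eta_true")
    if (!all(need %in% names(truth))) {
      abort("`truth` must have columns a, p, eta_true (or be a vector).")
    }
    m <- match(paste(out$a, out$p), paste(truth$a, truth$p))
    if (anyNA(m)) abort("`truth` is missing cells present in the predictions.")
    out$eta_true <- truth$eta_true[m]
  }
  out$abs_err <- abs(out$eta - out$eta_true)
  out$sq_err <- (out$eta - out$eta_true)^2
  out$is <- interval_score(out$lwr, out$upr, out$eta_true, level)
  out$width <- out$upr - out$lwr
  out$covered <- out$eta_true >= out$lwr & out$eta_true <= out$upr
  out
}

#' Aggregate per-cell scores into an estimation/forecasting report
#'
#' Cell scores are averaged first over replicates within each cell (when a
#' `replicate` column is present) and then over cells, separately for
#' estimation (in-sample) and forecasting cells.  All aggregates are means:
#' `mae`, `mse`, `is` (mean interval score), `width` (mean interval width)
#' and `coverage` (proportion of cells covered).
#'
#' @param cell_scores Output of [score_cells()], optionally row-bound over
#'   replicates with a `replicate` column, optionally carrying grouping
#'   columns named in `by`.
#' @param by Extra grouping columns (e.g. `"model"`), default none.
#' @return A tibble with one row per group x window (`window` is
#'   `"estimation"` or `"forecasting"`), columns `n_cells`, `n_replicates`,
#'   `mae`, `mse`, `is`, `width`, `coverage`.
#' @export
summarize_scores <- function(cell_scores, by = character()) {
  df <- as_tibble(cell_scores)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df$window <- ifelse(df$forecast, "forecasting", "estimation")
  per_cell <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "window", "a", "p")))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mae = mean(.data$abs_err), mse = mean(.data$sq_err),
      is = mean(.data$is), width = mean(.data$width),
      coverage = mean(.data$covered),
      .groups = "drop"
    )
  per_cell |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "window")))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_replicates = max(.data$n_replicates),
      mae = mean(.data$mae), mse = mean(.data$mse),
      is = mean(.data$is), width = mean(.data$width),
      coverage = mean(.data$coverage),
      .groups = "drop"
    )
}

#' Point-prediction scores (MAE and MSE)
#'
#' Convenience wrapper returning only the mean absolute and mean squared
#' error of a prediction set against truth, per window.
#'
#' @inheritParams score_cells
#' @return A tibble with columns `window`, `mae`, `mse`.
#' @export
point_scores <- function(predictions, truth) {
  summarize_scores(score_cells(predictions, truth))[
    , c("window", "mae", "mse")
  ]
}

#' Distributional scores (interval score, width, coverage)
#'
#' @inheritParams score_cells
#' @return A tibble with columns `window`, `is`, `width`, `coverage`.
#' @export
distributional_scores <- function(predictions, truth, level = NULL) {
  summarize_scores(score_cells(predictions, truth, level))[
    , c("window", "is", "width", "coverage")
  ]
}
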