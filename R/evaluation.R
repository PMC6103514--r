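#' Model evaluation statistics
#'
#' The fit/validation statistics used throughout: coefficient of
#' determination, mean residual, residual variance, and the combined error
#' measures
#'
#' * `e_bar   = mean(y - y')`
#' * `delta2  = sum((y - y')^2) / (n - 1)`
#' * `mse     = e_bar^2 + delta2`
#' * `rmse    = sqrt(mse)`
#' * `R^2     = 1 - sum((y - y')^2) / sum((y - mean(y))^2)`
#'
#' Two presentation notes, both deliberate. The source study's displayed
#' R-squared formula omits the squaring of both sums; the standard
#' squared-residual form above is implemented (the unsquared form is not
#' even sign-stable). And its validation tables print, under the label
#' "MSE", the value `sqrt(e_bar^2 + delta2)`; both quantities are
#' returned, with the table-compatible one labelled `rmse`.
#'
#' @name evaluation
NULL

#' Evaluation statistics from observed/predicted pairs
#'
#' @param observed numeric vector of measured total nitrogen.
#' @param predicted numeric vector of model predictions.
#' @return one-row tibble: `n`, `r_squared`, `e_bar`, `delta2`, `mse`,
#'   `rmse`.
#' @export
eval_stats <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  y <- observed[ok]; yp <- predicted[ok]
  n <- length(y)
  if (n < 2L) stop("need at least 2 observation/prediction pairs", call. = FALSE)
  res <- y - yp
  tss <- sum((y - mean(y))^2)
  e_bar <- mean(res)
  delta2 <- sum(res^2) / (n - 1)
  mse <- e_bar^2 + delta2
  tibble::tibble(
    n = n,
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    e_bar = e_bar, delta2 = delta2, mse = mse, rmse = sqrt(mse)
  )
}

#' Evaluate a fitted model on a sample table
#'
#' @param model a `"canopy_model"` (or a `"canopy_fit"`, whose model is
#'   used).
#' @param samples tibble with the model's channel columns, GS column if
#'   used, and `total_N`.
#' @return one-row tibble as in [eval_stats()].
#' @export
evaluate_model <- function(model, samples) {
  if (inherits(model, "canopy_fit")) model <- model$model
  stopifnot(inherits(model, "canopy_model"))
  if (!"total_N" %in% names(samples)) stop("samples lack a `total_N` column", call. = FALSE)
  eval_stats(samples$total_N, predict(model, samples))
}

#' Rank candidate models on modeling and validation criteria
#'
#' Six criteria per candidate: modeling R-squared and `|e_bar|`, and
#' validation R-squared, `|e_bar|`, `delta2` and `rmse`. Each criterion is
#' ranked (1 = best; higher R-squared is better, smaller magnitudes of the
#' others are better; ties share the lower rank), the default aggregate is
#' the sum of ranks, and the final order is ascending in the aggregate
#' (ties kept in input order and flagged).
#'
#' @param candidates tibble with one row per candidate and columns
#'   `model` (label), `mod_r_squared`, `mod_e_bar`, `val_r_squared`,
#'   `val_e_bar`, `val_delta2`, `val_rmse`.
#' @param aggregate function reducing the six per-criterion ranks to a
#'   score (default `sum`).
#' @return the input tibble with per-criterion rank columns, `score`,
#'   `order` and `tied`.
#' @export
rank_models <- function(candidates, aggregate = sum) {
  need <- c("mod_r_squared", "mod_e_bar", "val_r_squared", "val_e_bar",
            "val_delta2", "val_rmse")
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop("missing criterion column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(candidates) < 2L) stop("need at least 2 candidates to rank", call. = FALSE)
  if (any(!stats::complete.cases(candidates[, need])))
    stop("criterion values contain missing entries", call. = FALSE)
  rk <- function(v, higher_better = FALSE) {
    x <- if (higher_better) -v else v
    rank(x, ties.method = "min")
  }
  out <- candidates
  out$rank_mod_r2 <- rk(candidates$mod_r_squared, TRUE)
  out$rank_mod_e <- rk(abs(candidates$mod_e_bar))
  out$rank_val_r2 <- rk(candidates$val_r_squared, TRUE)
  out$rank_val_e <- rk(abs(candidates$val_e_bar))
  out$rank_val_d2 <- rk(abs(candidates$val_delta2))
  out$rank_val_rmse <- rk(abs(candidates$val_rmse))
  ranks <- out[, c("rank_mod_r2", "rank_mod_e", "rank_val_r2",
                   "rank_val_e", "rank_val_d2", "rank_val_rmse")]
  out$score <- apply(as.matrix(ranks), 1, aggregate)
  out$order <- rank(out$score, ties.method = "first")
  out$tied <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  dplyr::arrange(out, .data$order)
}
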