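#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a fitted nitrogen model
#'
#' @param x a `"canopy_fit"`.
#' @param ... ignored.
#' @return tibble with one row per coefficient: `term`, `estimate`.
#' @export
tidy.canopy_fit <- function(x, ...) {
  cf <- coef(x$model)
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' One-row fit summary
#'
#' @param x a `"canopy_fit"`.
#' @param ... ignored.
#' @return tibble with `family`, `system`, `gs_variant`, `method`, `n`,
#'   `r_squared`, `mean_residual`, `objective`, `converged`, `iterations`.
#' @export
glance.canopy_fit <- function(x, ...) {
  tibble::tibble(
    family = x$model$spec$family, system = x$model$spec$system,
    gs_variant = x$model$spec$gs_variant, method = x$method, n = x$n,
    r_squared = x$r_squared, mean_residual = x$mean_residual,
    objective = x$objective, converged = x$converged,
    iterations = x$iterations
  )
}

#' Per-sample fitted values and residuals
#'
#' @param x a `"canopy_fit"`.
#' @param ... ignored.
#' @return tibble with `observed`, `fitted`, `residual` (and, for EIV
#'   fits, the latent predictor adjustments as `adj_*` columns).
#' @export
augment.canopy_fit <- function(x, ...) {
  out <- tibble::tibble(observed = x$fitted + x$residuals,
                        fitted = x$fitted, residual = x$residuals)
  if (!is.null(x$latent)) {
    adj <- as.data.frame(x$latent)
    names(adj) <- paste0("adj_", names(adj))
    out <- dplyr::bind_cols(out, tibble::as_tibble(adj))
  }
  out
}

#' Observed-versus-predicted plot for a fit
#'
#' @param object a `"canopy_fit"`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.canopy_fit <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Predicted total N", y = "Measured total N",
      title = sprintf("%s / %s / GS %s (%s), R² = %.3f",
                      object$model$spec$family, object$model$spec$system,
                      object$model$spec$gs_variant, toupper(object$method),
                      object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Correlation-screen plot
#'
#' Bar chart of Pearson correlations from [pearson_screen()].
#'
#' @param screen tibble from [pearson_screen()].
#' @return a ggplot object.
#' @export
plot_screen <- function(screen) {
  df <- dplyr::filter(screen, !.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$predictor, abs(.data$r)),
                                   y = .data$r, fill = .data$sig_01)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson r with total N", fill = "p < 0.01") +
    ggplot2::theme_minimal()
}
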