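#' Prediction-model families
#'
#' Five parametric families relate a three-channel colour system (plus an
#' optional growth-status term) to total nitrogen `y`. With
#' `a_gs = b0 + b1 * GS` (or just `b0` when no GS variant is used):
#'
#' * linear:      `y = a_gs + sum(a_i * x_i)`
#' * reciprocal:  `y = a_gs + sum(a_i / x_i)`
#' * power:       `y = a_gs + a0 * prod(|x_i|^a_i)`
#' * logarithmic: `y = a_gs + a0 * ln|sum(a_i * x_i)|`
#' * exponential: `y = a_gs + a0 * exp(sum(a_i * x_i / x'_i))`
#'
#' where `x'_i` are per-channel ranges frozen from the modeling data
#' ([compute_normalizers()]). Note: the source study's model table prints
#' the reciprocal family with the same expression as the linear one — an
#' apparent typographical duplication; this package implements the
#' reciprocal family as `sum(a_i / x_i)`, consistent with its name.
#'
#' @name model_families
NULL

MODEL_FAMILIES <- c("linear", "reciprocal", "power", "logarithmic", "exponential")

#' Specify a prediction model
#'
#' @param family one of `"linear"`, `"reciprocal"`, `"power"`,
#'   `"logarithmic"`, `"exponential"`.
#' @param system colour system name (see [color_system()]), or `"custom"`
#'   when `channels` is supplied directly.
#' @param gs_variant growth-status term: `"none"`, `"MER"` or `"MCC"`.
#' @param channels optional explicit feature-column names (1-3), for
#'   non-standard predictor sets.
#' @return object of class `"canopy_model_spec"`.
#' @export
model_spec <- function(family = MODEL_FAMILIES,
                       system = c("Lab", "RGB", "HSI", "RLI", "custom"),
                       gs_variant = c("none", "MER", "MCC"),
                       channels = NULL) {
  family <- match.arg(family)
  system <- match.arg(system)
  gs_variant <- match.arg(gs_variant)
  if (is.null(channels)) {
    if (system == "custom") stop("`channels` must be given when system = \"custom\"", call. = FALSE)
    channels <- color_system(system)
  } else {
    stopifnot(is.character(channels), length(channels) >= 1L, length(channels) <= 3L)
  }
  structure(list(family = family, system = system,
                 gs_variant = gs_variant, channels = channels),
            class = "canopy_model_spec")
}

#' @export
print.canopy_model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s family, %s system (%s), GS = %s\n",
              x$family, x$system, paste(x$channels, collapse = ", "),
              x$gs_variant))
  invisible(x)
}

gs_column <- function(spec) {
  switch(spec$gs_variant, none = NULL, MER = "gs_mer", MCC = "gs_mcc")
}

n_free_coef <- function(spec) {
  k <- length(spec$channels)
  k + 1L +                                      # a_1..a_k, b0
    (spec$family %in% c("power", "logarithmic", "exponential")) +  # a0
    (spec$gs_variant != "none")                 # b1
}

#' Construct a fitted model object
#'
#' Usually produced by [fit_lsm()] / [fit_eiv()]; exposed so published or
#' externally estimated coefficients can be wrapped for prediction.
#'
#' @param spec a [model_spec()].
#' @param a vector of per-channel coefficients `a_1..a_k`.
#' @param b0 intercept.
#' @param a0 scale coefficient (power/logarithmic/exponential families).
#' @param b1 growth-status coefficient (when `gs_variant != "none"`).
#' @param normalizers named per-channel ranges (exponential family).
#' @return object of class `"canopy_model"`.
#' @export
canopy_model <- function(spec, a, b0, a0 = NULL, b1 = NULL, normalizers = NULL) {
  stopifnot(inherits(spec, "canopy_model_spec"),
            length(a) == length(spec$channels))
  needs_a0 <- spec$family %in% c("power", "logarithmic", "exponential")
  if (needs_a0 && is.null(a0)) stop(sprintf("family '%s' requires `a0`", spec$family), call. = FALSE)
  if (spec$gs_variant != "none" && is.null(b1)) stop("GS variant requires `b1`", call. = FALSE)
  if (spec$family == "exponential") {
    if (is.null(normalizers)) stop("exponential family requires `normalizers`", call. = FALSE)
    stopifnot(length(normalizers) == length(a), all(normalizers > 0))
  }
  cf <- c(a0 = if (needs_a0) unname(a0), stats::setNames(unname(a), paste0("a", seq_along(a))),
          b0 = unname(b0), b1 = if (spec$gs_variant != "none") unname(b1))
  if (any(!is.finite(cf))) stop("model coefficients must be finite", call. = FALSE)
  structure(list(spec = spec, a = unname(a), b0 = unname(b0),
                 a0 = if (needs_a0) unname(a0) else NULL,
                 b1 = if (spec$gs_variant != "none") unname(b1) else NULL,
                 normalizers = if (spec$family == "exponential") unname(normalizers) else NULL),
            class = "canopy_model")
}

#' @export
print.canopy_model <- function(x, ...) {
  print(x$spec)
  cf <- coef(x)
  cat("  coefficients:", paste(sprintf("%s = %.4g", names(cf), cf), collapse = ", "), "\n")
  if (!is.null(x$normalizers))
    cat("  normalizers:", paste(sprintf("%.4g", x$normalizers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.canopy_model <- function(object, ...) {
  c(if (!is.null(object$a0)) c(a0 = object$a0),
    stats::setNames(object$a, paste0("a", seq_along(object$a))),
    b0 = object$b0,
    if (!is.null(object$b1)) c(b1 = object$b1))
}

# Core evaluator: X is an n x k matrix of channel values, gs a vector or NULL.
eval_family <- function(family, X, gs, a, b0, a0, b1, normalizers,
                        check_domain = TRUE) {
  ags <- b0 + if (!is.null(gs) && !is.null(b1)) b1 * gs else 0
  switch(family,
    linear = ags + drop(X %*% a),
    reciprocal = {
      if (check_domain && any(X == 0)) stop("reciprocal family: predictor value 0 encountered", call. = FALSE)
      ags + drop((1 / X) %*% a)
    },
    power = {
      if (any(X == 0)) {
        if (check_domain && any(sweep(X == 0, 2, a < 0, `&`)))
          stop("power family: zero predictor with negative exponent", call. = FALSE)
        ags + a0 * apply(sweep(abs(X), 2, a, `^`), 1, prod)
      } else {
        ags + a0 * exp(drop(log(abs(X)) %*% a))
      }
    },
    logarithmic = {
      s <- drop(X %*% a)
      if (check_domain && any(s == 0)) stop("logarithmic family: sum(a_i x_i) = 0 encountered", call. = FALSE)
      ags + a0 * log(abs(s))
    },
    exponential = ags + a0 * exp(pmin(drop(X %*% (a / normalizers)), 700))
  )
}

#' Predict total nitrogen for sample records
#'
#' @param object a `"canopy_model"`.
#' @param newdata tibble of sample records containing the model's channel
#'   columns (and `gs_mer`/`gs_mcc` if the model uses a GS term).
#' @param ... ignored.
#' @return numeric vector of predicted total nitrogen.
#' @examples
#' m <- reference_model()
#' predict(m, tibble::tibble(mean_L = 0, mean_a = 0, mean_b = 0, gs_mcc = 0))
#' @export
predict.canopy_model <- function(object, newdata, ...) {
  spec <- object$spec
  miss <- setdiff(spec$channels, names(newdata))
  if (length(miss)) stop("newdata lacks channel column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[, spec$channels, drop = FALSE])
  gcol <- gs_column(spec)
  gs <- if (!is.null(gcol)) {
    if (!gcol %in% names(newdata)) stop("newdata lacks the `", gcol, "` column", call. = FALSE)
    newdata[[gcol]]
  }
  eval_family(spec$family, X, gs, object$a, object$b0, object$a0, object$b1,
              object$normalizers)
}

#' Enumerate candidate model specifications
#'
#' Cross-product of the five families, four colour systems and three
#' growth-status variants (60 specs), optionally filtered.
#'
#' @param family,system,gs_variant optional filters (vectors of allowed
#'   values).
#' @return tibble with columns `family`, `system`, `gs_variant` and a
#'   `spec` list-column of [model_spec()] objects.
#' @export
model_grid <- function(family = MODEL_FAMILIES,
                       system = c("RGB", "HSI", "Lab", "RLI"),
                       gs_variant = c("none", "MER", "MCC")) {
  g <- tidyr::expand_grid(family = family, system = system,
                          gs_variant = gs_variant)
  g$spec <- purrr::pmap(g, function(family, system, gs_variant)
    model_spec(family, system, gs_variant))
  g
}

#' The published optimal model (reference coefficients)
#'
#' The exponential Lab model with the `GS_MCC` term and the published
#' errors-in-variables coefficients
#' `y = 237.374 exp(-(4.471 L/L' + 11.927 a/a' + 2.782 b/b'))
#'  + 26.248 GS_MCC - 4.274`.
#' The channel ranges `L', a', b'` of the original 48-sample modeling set
#' were never published, so the packaged model defaults to unit
#' normalizers: its channel inputs are then interpreted as the already
#' normalized terms `x_i / x'_i`. Supply `normalizers` to use raw channel
#' means from your own modeling set.
#'
#' @param normalizers optional per-channel ranges (L, a, b order).
#' @return a `"canopy_model"`.
#' @export
reference_model <- function(normalizers = c(1, 1, 1)) {
  canopy_model(model_spec("exponential", "Lab", "MCC"),
               a = c(-4.471, -11.927, -2.782), b0 = -4.274,
               a0 = 237.374, b1 = 26.248, normalizers = normalizers)
}

#' Serialize / restore a fitted model
#'
#' Models round-trip through a small JSON document holding the family,
#' system, GS variant, coefficients and normalizers.
#'
#' @param model a `"canopy_model"`.
#' @param path file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "canopy_model"))
  obj <- list(family = model$spec$family, system = model$spec$system,
              gs_variant = model$spec$gs_variant,
              channels = model$spec$channels,
              a = model$a, b0 = model$b0, a0 = model$a0, b1 = model$b1,
              normalizers = model$normalizers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(o$family, o$system, o$gs_variant,
                     channels = if (o$system == "custom") o$channels)
  canopy_model(spec, a = o$a, b0 = o$b0, a0 = o$a0, b1 = o$b1,
               normalizers = o$normalizers)
}
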