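#' Parameter estimation
#'
#' Two estimators for any [model_spec()]:
#'
#' * [fit_lsm()] — nonlinear least squares. The parameters entering the
#'   model linearly (`b0`, `b1`, `a0`) are profiled out exactly, so the
#'   optimizer only searches the per-channel exponents/slopes; linear and
#'   reciprocal families reduce entirely to closed-form linear regression.
#' * [fit_eiv()] — an errors-in-variables (measurement-error) estimator.
#'   Colour means and growth-status ratios are themselves estimates
#'   derived from an imperfect segmentation, so the predictors carry
#'   error; ordinary least squares is then attenuated/biased. The EIV
#'   estimator minimizes the weighted orthogonal objective
#'   `sum_i [ (y_i - f(xi_i; c))^2 / s2_y + sum_j (z_ij - xi_ij)^2 / s2_j ]`
#'   jointly over the coefficients `c` and latent true predictors `xi_i`,
#'   with error variances `s2` supplied or estimated
#'   ([estimate_sigma()]).
#'
#' @name fitting
NULL

#' Fitting control parameters
#'
#' @param n_starts number of seeded random restarts for nonlinear families.
#' @param seed seed for the restart draws (local; the global RNG stream is
#'   left untouched).
#' @param maxit,reltol passed to the inner optimizer.
#' @param eiv_max_iter maximum alternating iterations of the EIV loop.
#' @param eiv_tol objective-decrease tolerance ending the EIV loop.
#' @param polish run the profile-likelihood polish (Newton refinement) at
#'   the end of an EIV fit.
#' @return list of class `"fit_control"`.
#' @export
fit_control <- function(n_starts = 5L, seed = 1L, maxit = 1000L,
                        reltol = 1e-14, eiv_max_iter = 25L, eiv_tol = 1e-9,
                        polish = TRUE) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxit = as.integer(maxit), reltol = reltol,
                 eiv_max_iter = as.integer(eiv_max_iter),
                 eiv_tol = eiv_tol,
                 polish = isTRUE(polish)), class = "fit_control")
}

# Run code with a temporary RNG state so fitting is deterministic without
# disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fit_data <- function(spec, samples, normalizers) {
  miss <- setdiff(spec$channels, names(samples))
  if (length(miss)) stop("samples lack channel column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"total_N" %in% names(samples)) stop("samples lack a `total_N` column", call. = FALSE)
  X <- as.matrix(samples[, spec$channels, drop = FALSE])
  gcol <- gs_column(spec)
  gs <- if (!is.null(gcol)) {
    if (!gcol %in% names(samples)) stop("samples lack the `", gcol, "` column", call. = FALSE)
    samples[[gcol]]
  }
  y <- samples$total_N
  keep <- stats::complete.cases(X, y, if (is.null(gs)) rep(0, length(y)) else gs)
  X <- X[keep, , drop = FALSE]; y <- y[keep]; gs <- gs[keep]
  if (spec$family == "reciprocal" && any(X == 0))
    stop("reciprocal family: predictor value 0 in the modeling data", call. = FALSE)
  if (spec$family == "power" && any(X == 0))
    stop("power family: predictor value 0 in the modeling data", call. = FALSE)
  if (spec$family == "exponential" && is.null(normalizers))
    normalizers <- compute_normalizers(samples[keep, ], spec$channels)
  list(X = X, gs = gs, y = y, normalizers = unname(normalizers))
}

# Nonlinear core g_i(a) of the three non-closed-form families.
family_core <- function(family, X, normalizers) {
  switch(family,
    power = {
      LX <- log(abs(X))
      function(a) exp(drop(LX %*% a))
    },
    logarithmic = function(a) {
      s <- drop(X %*% a)
      if (any(s == 0)) return(rep(NA_real_, nrow(X)))
      log(abs(s))
    },
    exponential = {
      Xn <- sweep(X, 2, normalizers, `/`)
      function(a) exp(pmin(drop(Xn %*% a), 700))
    }
  )
}

# Profile SSE over the linear parameters (b0, b1, a0) for a given nonlinear
# coefficient vector a; returns SSE and the profiled linear coefficients.
profile_linear <- function(g, gs, y) {
  if (any(!is.finite(g))) return(list(sse = Inf))
  D <- cbind(1, gs, g)
  fit <- tryCatch(stats::lm.fit(D, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(list(sse = Inf))
  cf <- fit$coefficients
  k <- if (is.null(gs)) 0L else 1L
  list(sse = sum(fit$residuals^2), b0 = cf[1],
       b1 = if (k) cf[2] else NULL, a0 = cf[2 + k],
       fitted = y - fit$residuals)
}

lsm_starts <- function(family, X, gs, y, normalizers, n_starts) {
  k <- ncol(X)
  starts <- list()
  base <- tryCatch({
    r <- stats::lm.fit(cbind(1, gs), y)$residuals
    if (all(r > 0) || all(r < 0)) {
      Z <- switch(family, power = log(abs(X)),
                  exponential = sweep(X, 2, normalizers, `/`), X)
      stats::lm.fit(cbind(1, Z), log(abs(r)))$coefficients[-1]
    } else NULL
  }, error = function(e) NULL)
  if (!is.null(base) && all(is.finite(base))) starts <- c(starts, list(unname(base)))
  lin <- tryCatch(stats::lm.fit(cbind(1, X, gs), y)$coefficients[2:(k + 1)],
                  error = function(e) NULL)
  if (!is.null(lin) && all(is.finite(lin))) {
    d <- unname(lin)
    nd <- sqrt(sum(d^2))
    if (nd > 0) starts <- c(starts, list(d / nd), list(-d / nd))
  }
  rand <- lapply(seq_len(n_starts), function(i) stats::rnorm(k, 0, 1))
  c(starts, rand)
}

optimize_core <- function(sse_fn, starts, control) {
  best <- NULL
  for (a0 in starts) {
    if (!all(is.finite(sse_fn(a0)))) next
    for (method in c("BFGS", "Nelder-Mead")) {
      o <- tryCatch(
        stats::optim(a0, sse_fn, method = method,
                     control = list(maxit = control$maxit, reltol = control$reltol)),
        error = function(e) NULL)
      if (!is.null(o) && is.finite(o$value) &&
          (is.null(best) || o$value < best$value)) best <- o
      if (!is.null(o)) a0 <- o$par  # chain NM after BFGS from its optimum
    }
  }
  best
}

new_fit <- function(model, method, y, fitted, converged, iterations,
                    extra = list()) {
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  structure(c(list(
    model = model, method = method, n = length(y),
    objective = sum(res^2), fitted = fitted, residuals = res,
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    mean_residual = mean(res),
    converged = converged, iterations = iterations), extra),
    class = "canopy_fit")
}

#' Fit a model by (nonlinear) least squares
#'
#' Linear and reciprocal families are solved in closed form; power,
#' logarithmic and exponential families by multi-start quasi-Newton
#' minimization of the profiled sum of squares (warm starts from
#' log-linearized fits plus seeded random restarts).
#'
#' @param spec a [model_spec()].
#' @param samples modeling tibble with the spec's channel columns,
#'   `total_N`, and `gs_mer`/`gs_mcc` if used.
#' @param normalizers optional fixed channel ranges for the exponential
#'   family; computed from `samples` by default and frozen into the model.
#' @param control a [fit_control()].
#' @return object of class `"canopy_fit"` (see [tidy.canopy_fit()],
#'   [glance.canopy_fit()]).
#' @export
fit_lsm <- function(spec, samples, normalizers = NULL, control = fit_control()) {
  d <- fit_data(spec, samples, normalizers)
  if (length(d$y) < n_free_coef(spec) + 1L)
    stop("too few samples for the number of free coefficients", call. = FALSE)
  X <- d$X; gs <- d$gs; y <- d$y
  k <- ncol(X)

  if (spec$family %in% c("linear", "reciprocal")) {
    Tx <- if (spec$family == "reciprocal") 1 / X else X
    D <- cbind(1, Tx, gs)
    fit <- stats::lm.fit(D, y)
    cf <- fit$coefficients
    if (any(is.na(cf))) stop("singular design: coefficients not estimable", call. = FALSE)
    model <- canopy_model(spec, a = unname(cf[2:(k + 1)]), b0 = unname(cf[1]),
                          b1 = if (!is.null(gs)) unname(cf[k + 2]))
    return(new_fit(model, "lsm", y, y - fit$residuals, TRUE, 1L))
  }

  core <- family_core(spec$family, X, d$normalizers)
  sse_fn <- function(a) profile_linear(core(a), gs, y)$sse
  o <- with_local_seed(control$seed, {
    starts <- lsm_starts(spec$family, X, gs, y, d$normalizers, control$n_starts)
    optimize_core(sse_fn, starts, control)
  })
  if (is.null(o)) stop("least-squares optimization failed from every start", call. = FALSE)
  converged <- o$convergence == 0
  np <- newton_polish(function(a) { v <- sse_fn(a); if (is.finite(v)) v else Inf },
                      o$par)
  a <- if (np$value <= o$value) np$par else o$par
  prof <- profile_linear(core(a), gs, y)
  model <- canopy_model(spec, a = a, b0 = prof$b0, a0 = prof$a0,
                        b1 = prof$b1, normalizers = d$normalizers)
  if (!converged) warning("least-squares fit did not report convergence; result flagged", call. = FALSE)
  new_fit(model, "lsm", y, prof$fitted, converged, o$counts[1])
}

#' Error-variance specification for EIV fitting
#'
#' @param sigma_y response error variance.
#' @param sigma_x named vector of predictor error variances (channel
#'   columns, plus the GS column when used). Zero entries are floored to a
#'   tiny value, in which limit the EIV fit coincides with least squares.
#' @return list of class `"eiv_sigma"`.
#' @export
eiv_sigma <- function(sigma_y, sigma_x) {
  stopifnot(length(sigma_y) == 1L, sigma_y > 0, all(sigma_x >= 0))
  structure(list(y = unname(sigma_y), x = sigma_x), class = "eiv_sigma")
}

#' Default error-variance heuristic
#'
#' The segmentation's accuracy bounds set the predictor error scale:
#' colour-channel variances default to `(0.03 * mean(|x|))^2` (the 3%
#' colour-error bound) and growth-status variances to
#' `(0.05 * mean(gs))^2` (the 5% pixel-count bound). The response variance
#' defaults to the least-squares residual variance (floored at 1e-8).
#' Fully overridable via [eiv_sigma()].
#'
#' @param samples modeling tibble.
#' @param spec a [model_spec()].
#' @param lsm_fit optional existing [fit_lsm()] result for the residual
#'   variance; fitted on the spot when absent.
#' @param control a [fit_control()].
#' @return an [eiv_sigma()].
#' @export
estimate_sigma <- function(samples, spec, lsm_fit = NULL,
                           control = fit_control()) {
  if (nrow(samples) < 10L) stop("need at least 10 samples to estimate error variances", call. = FALSE)
  cols <- c(spec$channels, gs_column(spec))
  sx <- vapply(cols, function(cl) {
    frac <- if (cl %in% c("gs_mer", "gs_mcc")) 0.05 else 0.03
    (frac * mean(abs(samples[[cl]])))^2
  }, numeric(1))
  if (is.null(lsm_fit)) lsm_fit <- fit_lsm(spec, samples, control = control)
  sy <- max(sum(lsm_fit$residuals^2) / max(lsm_fit$n - n_free_coef(spec), 1), 1e-8)
  eiv_sigma(sy, sx)
}

# f(xi; c) and its gradient wrt xi, vectorized over samples. Z holds the
# channel columns and (optionally) the GS column last.
eiv_predict <- function(family, Z, k, has_gs, a, b0, a0, b1, normalizers) {
  Xc <- Z[, seq_len(k), drop = FALSE]
  base <- eval_family(family, Xc, NULL, a, 0, a0, NULL, normalizers,
                      check_domain = FALSE)
  base + b0 + if (has_gs) b1 * Z[, k + 1L] else 0
}

eiv_gradient <- function(family, Z, k, has_gs, a, a0, b1, normalizers) {
  Xc <- Z[, seq_len(k), drop = FALSE]
  n <- nrow(Z)
  arow <- function(v) matrix(v, n, k, byrow = TRUE)
  G <- switch(family,
    linear = arow(a),
    reciprocal = (-1 / Xc^2) * arow(a),
    power = {
      core <- a0 * exp(drop(log(abs(Xc)) %*% a))
      core * arow(a) / Xc
    },
    logarithmic = {
      s <- drop(Xc %*% a)
      (a0 / s) * arow(a)
    },
    exponential = {
      core <- a0 * exp(pmin(drop(Xc %*% (a / normalizers)), 700))
      core * arow(a / normalizers)
    })
  if (has_gs) G <- cbind(G, b1)
  G
}

# Solve the latent predictors xi_i given coefficients: per-sample damped
# Gauss-Newton, vectorized across samples (rank-one Sherman-Morrison solve).
latent_solve <- function(family, Zobs, k, has_gs, a, b0, a0, b1, normalizers,
                         sy, sx, xi = Zobs, maxit = 40L, tol = 1e-13) {
  n <- nrow(Zobs)
  SX <- matrix(sx, n, length(sx), byrow = TRUE)   # per-column variances
  if (family == "linear") {
    # f is linear in the latents, so the inner minimization is exact:
    # xi* = z + (sx o c) r / (sy + sum c^2 sx), objective r^2 / (sy + ...)
    cc <- c(a, if (has_gs) b1)
    r <- attr(Zobs, "y") - b0 - drop(Zobs %*% cc)
    den <- sy + sum(cc^2 * sx)
    xi <- Zobs + (matrix(cc * sx, n, length(sx), byrow = TRUE)) * (r / den)
    h <- r^2 / den
    return(list(xi = xi, per_obj = h, objective = sum(h)))
  }
  per_obj <- function(xi) {
    f <- eiv_predict(family, xi, k, has_gs, a, b0, a0, b1, normalizers)
    (Zobs_y - f)^2 / sy + rowSums((Zobs - xi)^2 / SX)
  }
  Zobs_y <- attr(Zobs, "y")
  h <- per_obj(xi)
  if (any(!is.finite(h)))
    return(list(xi = xi, per_obj = h, objective = Inf))
  scale_xi <- 1 + max(abs(Zobs))
  for (it in seq_len(maxit)) {
    f <- eiv_predict(family, xi, k, has_gs, a, b0, a0, b1, normalizers)
    G <- eiv_gradient(family, xi, k, has_gs, a, a0, b1, normalizers)
    u <- Zobs_y - f
    V <- Zobs - xi
    GS_ <- G * SX
    W <- GS_ * (u / sy) + V                      # D^{-1} r
    Gw <- rowSums(G * W)
    s <- rowSums(G * GS_)
    Delta <- W - GS_ * (Gw / (sy + s))
    Delta[!is.finite(Delta)] <- 0
    if (max(abs(Delta)) < 1e-11 * scale_xi) break
    # damped per-sample acceptance
    alpha <- rep(1, nrow(xi)); accepted <- rep(FALSE, nrow(xi))
    xi_new <- xi; h_new <- h
    for (bt in 1:12) {
      trial <- xi + alpha * Delta
      ht <- per_obj(trial)
      ok <- !accepted & is.finite(ht) & ht <= h * (1 + 1e-12) + 1e-300
      xi_new[ok, ] <- trial[ok, , drop = FALSE]
      h_new[ok] <- ht[ok]
      accepted <- accepted | ok
      if (all(accepted)) break
      alpha <- ifelse(accepted, alpha, alpha / 2)
    }
    dec <- sum(h) - sum(h_new)
    xi <- xi_new; h <- h_new
    if (dec < tol * (1 + abs(sum(h)))) break
  }
  list(xi = xi, per_obj = h, objective = sum(h))
}

pack_coef <- function(m) c(m$a, m$b0, m$a0, m$b1)

# d f(xi; c) / d c at fixed latents, columns in pack_coef order
# (a_1..a_k, b0, a0?, b1?); used for the envelope-theorem gradient of the
# profiled EIV objective.
eiv_coef_grad <- function(family, xi, k, has_gs, a, a0, normalizers) {
  Xc <- xi[, seq_len(k), drop = FALSE]
  n <- nrow(xi)
  switch(family,
    linear = cbind(Xc, 1),
    reciprocal = cbind(1 / Xc, 1),
    power = {
      g <- exp(drop(log(abs(Xc)) %*% a))
      cbind((a0 * g) * log(abs(Xc)), 1, g)
    },
    logarithmic = {
      s <- drop(Xc %*% a)
      cbind((a0 / s) * Xc, 1, log(abs(s)))
    },
    exponential = {
      g <- exp(pmin(drop(Xc %*% (a / normalizers)), 700))
      cbind((a0 * g) * (Xc / matrix(normalizers, n, k, byrow = TRUE)), 1, g)
    }) |>
    (\(M) if (has_gs) cbind(M, xi[, k + 1L]) else M)()
}

unpack_coef <- function(theta, spec) {
  k <- length(spec$channels)
  has_a0 <- spec$family %in% c("power", "logarithmic", "exponential")
  has_b1 <- spec$gs_variant != "none"
  i <- k + 1L
  list(a = theta[seq_len(k)], b0 = theta[i],
       a0 = if (has_a0) theta[i <- i + 1L],
       b1 = if (has_b1) theta[i + 1L])
}

# Central finite differences; cheap at <= 6 parameters.
fd_grad <- function(fn, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * (1 + abs(x))
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (fn(x + e) - fn(x - e)) / (2 * h[i])
  }, numeric(1))
}

fd_hess <- function(fn, x, h = NULL) {
  if (is.null(h)) h <- 1e-4 * (1 + abs(x))
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- numeric(p); ei[i] <- h[i]
    ej <- numeric(p); ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

newton_polish <- function(fn, par, iters = 4L) {
  val <- fn(par)
  for (it in seq_len(iters)) {
    g <- fd_grad(fn, par)
    H <- fd_hess(fn, par)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    alpha <- 1
    repeat {
      cand <- par + alpha * step
      v <- fn(cand)
      if (is.finite(v) && v < val) { par <- cand; val <- v; break }
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (sqrt(sum(g^2)) < 1e-12 * (1 + abs(val))) break
  }
  list(par = par, value = val)
}

#' Fit a model by the errors-in-variables estimator
#'
#' Minimizes the weighted orthogonal objective over coefficients and
#' latent true predictors jointly: alternating updates (exact/damped
#' Gauss-Newton latent solve, then a coefficient refit on the latents),
#' warm-started at the least-squares solution, followed by a Newton polish
#' of the profiled objective. The objective is non-increasing across the
#' alternating iterations (recorded in `$trace`).
#'
#' @inheritParams fit_lsm
#' @param sigma an [eiv_sigma()]; estimated via [estimate_sigma()] when
#'   omitted.
#' @return a `"canopy_fit"` with extra fields `latent` (the adjusted
#'   predictor matrix), `trace` (objective per iteration), `sigma` and
#'   `eiv_objective`.
#' @export
fit_eiv <- function(spec, samples, sigma = NULL, normalizers = NULL,
                    control = fit_control()) {
  d <- fit_data(spec, samples, normalizers)
  lsm <- fit_lsm(spec, samples, normalizers = d$normalizers, control = control)
  if (is.null(sigma)) sigma <- estimate_sigma(samples, spec, lsm_fit = lsm,
                                              control = control)
  stopifnot(inherits(sigma, "eiv_sigma"))
  k <- length(spec$channels)
  has_gs <- spec$gs_variant != "none"
  q <- k + has_gs
  sx <- as.numeric(sigma$x)
  if (length(sx) != q) stop(sprintf("sigma$x must have %d entries (channels%s)", q,
                                    if (has_gs) " + GS" else ""), call. = FALSE)
  floor_sx <- 1e-10 * pmax(colMeans(abs(cbind(d$X, if (has_gs) d$gs)))^2, 1e-8)
  sx <- pmax(sx, floor_sx)
  sy <- sigma$y

  Zobs <- cbind(d$X, if (has_gs) d$gs)
  attr(Zobs, "y") <- d$y
  m <- lsm$model
  theta <- pack_coef(m)

  objective_at <- function(theta, xi_start) {
    cc <- unpack_coef(theta, spec)
    latent_solve(spec$family, Zobs, k, has_gs, cc$a, cc$b0, cc$a0, cc$b1,
                 d$normalizers, sy, sx, xi = xi_start)
  }

  xi <- Zobs
  trace <- numeric(0)
  ls <- objective_at(theta, xi)
  xi <- ls$xi
  obj <- ls$objective
  trace <- c(trace, obj)
  it <- 0L
  converged <- FALSE
  core <- NULL
  for (it in seq_len(control$eiv_max_iter)) {
    # coefficient step on the current latents (response part only; the
    # latent part of the objective is constant in c)
    cc <- unpack_coef(theta, spec)
    Xi_chan <- xi[, seq_len(k), drop = FALSE]
    gs_xi <- if (has_gs) xi[, k + 1L]
    if (spec$family %in% c("linear", "reciprocal")) {
      Tx <- if (spec$family == "reciprocal") 1 / Xi_chan else Xi_chan
      cf <- stats::lm.fit(cbind(1, Tx, gs_xi), d$y)$coefficients
      if (!any(is.na(cf)))
        theta_new <- c(cf[2:(k + 1)], cf[1], if (has_gs) cf[k + 2])
      else theta_new <- theta
    } else {
      core <- family_core(spec$family, Xi_chan, d$normalizers)
      sse_fn <- function(a) profile_linear(core(a), gs_xi, d$y)$sse
      o <- tryCatch(stats::optim(cc$a, sse_fn, method = "BFGS",
                                 control = list(maxit = 60, reltol = 1e-10)),
                    error = function(e) NULL)
      if (!is.null(o) && is.finite(o$value)) {
        prof <- profile_linear(core(o$par), gs_xi, d$y)
        theta_new <- c(o$par, prof$b0, prof$a0, prof$b1)
      } else theta_new <- theta
    }
    ls_new <- objective_at(theta_new, xi)
    if (ls_new$objective <= obj) {
      theta <- theta_new; xi <- ls_new$xi
      dec <- obj - ls_new$objective
      obj <- ls_new$objective
    } else dec <- 0
    trace <- c(trace, obj)
    if (dec < control$eiv_tol * (1 + abs(obj))) { converged <- TRUE; break }
  }

  if (control$polish) {
    # profiled objective Q(c) = sum_i min_xi [...]; the inner solves are
    # warm-started from the latest latents, which only affects speed, not
    # the profiled value (the inner problem is solved to tolerance)
    xi_warm <- xi
    prof_fn <- function(th) {
      ls <- tryCatch(objective_at(th, xi_warm), error = function(e) NULL)
      if (is.null(ls) || !is.finite(ls$objective)) return(Inf)
      xi_warm <<- ls$xi
      ls$objective
    }
    prof_gr <- function(th) {
      ls <- tryCatch(objective_at(th, xi_warm), error = function(e) NULL)
      if (is.null(ls)) return(rep(0, length(th)))
      xi_warm <<- ls$xi
      cc <- unpack_coef(th, spec)
      f <- eiv_predict(spec$family, ls$xi, k, has_gs, cc$a, cc$b0, cc$a0,
                       cc$b1, d$normalizers)
      Dc <- eiv_coef_grad(spec$family, ls$xi, k, has_gs, cc$a, cc$a0,
                          d$normalizers)
      drop(crossprod(Dc, -2 * (d$y - f) / sy))
    }
    o <- tryCatch(stats::optim(theta, prof_fn, gr = prof_gr, method = "BFGS",
                               control = list(maxit = control$maxit,
                                              reltol = control$reltol)),
                  error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) && o$value <= obj) {
      theta <- o$par; obj <- o$value
    }
    # Newton refinement on the profiled objective: Hessian by finite
    # differences of the analytic gradient
    for (nit in 1:3) {
      g <- prof_gr(theta)
      if (!all(is.finite(g)) || sqrt(sum(g^2)) < 1e-11 * (1 + abs(obj))) break
      p <- length(theta)
      H <- matrix(0, p, p)
      hh <- 1e-6 * (1 + abs(theta))
      for (j in seq_len(p)) {
        e <- numeric(p); e[j] <- hh[j]
        H[, j] <- (prof_gr(theta + e) - prof_gr(theta - e)) / (2 * hh[j])
      }
      H <- (H + t(H)) / 2
      step <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      alpha <- 1; improved <- FALSE
      while (alpha > 1e-8) {
        v <- prof_fn(theta + alpha * step)
        if (is.finite(v) && v < obj) {
          theta <- theta + alpha * step; obj <- v; improved <- TRUE; break
        }
        alpha <- alpha / 2
      }
      if (!improved) break
    }
    ls <- objective_at(theta, xi_warm)
    xi <- ls$xi; obj <- ls$objective
    trace <- c(trace, obj)
  }

  cc <- unpack_coef(theta, spec)
  model <- canopy_model(spec, a = cc$a, b0 = cc$b0, a0 = cc$a0, b1 = cc$b1,
                        normalizers = d$normalizers)
  fitted <- eiv_predict(spec$family, Zobs, k, has_gs, cc$a, cc$b0, cc$a0,
                        cc$b1, d$normalizers)
  colnames(xi) <- c(spec$channels, gs_column(spec))
  new_fit(model, "eiv", d$y, fitted, converged, it,
          extra = list(latent = xi, trace = trace, sigma = sigma,
                       eiv_objective = obj))
}

#' @export
print.canopy_fit <- function(x, ...) {
  cat(sprintf("Canopy nitrogen model fit (%s, n = %d)\n", toupper(x$method), x$n))
  print(x$model)
  cat(sprintf("  R^2 = %.4f, mean residual = %.4f, SSE = %.4g%s\n",
              x$r_squared, x$mean_residual, x$objective,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}
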