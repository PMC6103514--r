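#' Synthetic fixtures with known ground truth
#'
#' No field imagery ships with the package, so every image-processing and
#' fitting routine is exercised on generated data with exact ground truth:
#' [render_scene()] paints a plant blob over a soil background (with an
#' optional darker distractor plant) directly in Lab — guaranteeing the
#' b-channel plant/soil separation and the L-channel plant/distractor
#' separation that the segmentation cascade exploits — and converts to
#' RGB; [generate_samples()] draws predictor/response tables from a known
#' model with controllable noise in both predictors and response.
#' Everything is deterministic given the seed.
#'
#' @name synthetic_fixtures
NULL

#' Specify a synthetic field scene
#'
#' Default colours (Lab): plant L = 65, a = -25, b = 40; soil L = 45,
#' a = 8, b = 18; distractor plant L = 30, a = -20, b = 35. The plant and
#' soil are separated in the b channel and the plant and distractor in L,
#' which is the mechanism the cascade relies on in real field frames.
#' The default frame is the 1024 x 768 field-camera format.
#'
#' @param width,height frame size in pixels.
#' @param shape plant shape: `"disk"`, `"ellipse"` or `"blob"` (a union of
#'   overlapping disks).
#' @param center plant centre `(x, y)` in 0-based pixel coordinates
#'   (defaults to the frame centre).
#' @param plant_radius plant radius in pixels (major semi-axis for
#'   ellipse/blob).
#' @param plant_lab,soil_lab,distractor_lab Lab colour means.
#' @param jitter per-channel Lab noise SD.
#' @param distractor add a darker distractor plant.
#' @param distractor_center,distractor_radius distractor geometry.
#' @param seed RNG seed for the colour jitter and blob geometry.
#' @return list of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 1024L, height = 768L,
                       shape = c("disk", "ellipse", "blob"),
                       center = NULL, plant_radius = NULL,
                       plant_lab = c(65, -25, 40),
                       soil_lab = c(45, 8, 18),
                       distractor_lab = c(30, -20, 35),
                       jitter = c(2, 2, 2),
                       distractor = FALSE,
                       distractor_center = NULL, distractor_radius = NULL,
                       seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(plant_radius)) plant_radius <- round(min(width, height) / 4)
  if (is.null(center)) center <- c((width - 1) / 2, (height - 1) / 2)
  if (plant_radius >= min(width, height) / 2)
    stop("plant larger than the frame", call. = FALSE)
  if (is.null(distractor_center)) distractor_center <- c(width * 0.15, height * 0.2)
  if (is.null(distractor_radius)) distractor_radius <- round(plant_radius / 3)
  structure(list(width = as.integer(width), height = as.integer(height),
                 shape = shape, center = center, plant_radius = plant_radius,
                 plant_lab = plant_lab, soil_lab = soil_lab,
                 distractor_lab = distractor_lab, jitter = jitter,
                 distractor = isTRUE(distractor),
                 distractor_center = distractor_center,
                 distractor_radius = distractor_radius,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

shape_mask <- function(spec) {
  xs <- 0:(spec$width - 1); ys <- 0:(spec$height - 1)
  dx <- outer(rep(1, spec$height), xs - spec$center[1])
  dy <- outer(ys - spec$center[2], rep(1, spec$width))
  r <- spec$plant_radius
  switch(spec$shape,
    disk = (dx^2 + dy^2) <= r^2,
    ellipse = (dx / r)^2 + (dy / (0.6 * r))^2 <= 1,
    blob = {
      # union of the main disk and satellite disks at seeded angles
      m <- (dx^2 + dy^2) <= r^2
      ang <- stats::runif(4, 0, 2 * pi)
      for (aa in ang) {
        cx <- spec$center[1] + 0.7 * r * cos(aa)
        cy <- spec$center[2] + 0.7 * r * sin(aa)
        m <- m | ((outer(rep(1, spec$height), xs - cx)^2 +
                   outer(ys - cy, rep(1, spec$width))^2) <= (0.45 * r)^2)
      }
      m
    })
}

#' Render a synthetic scene and its ground-truth mask
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (RGB array), `mask` (ground-truth 0/1
#'   matrix of plant pixels), `distractor_mask`, and the spec.
#' @examples
#' sc <- render_scene(scene_spec(width = 64, height = 64, plant_radius = 20))
#' dim(sc$image); sum(sc$mask)
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    plant <- shape_mask(spec)
    dmask <- matrix(FALSE, spec$height, spec$width)
    if (spec$distractor) {
      xs <- 0:(spec$width - 1); ys <- 0:(spec$height - 1)
      dmask <- (outer(rep(1, spec$height), xs - spec$distractor_center[1])^2 +
                outer(ys - spec$distractor_center[2], rep(1, spec$width))^2) <=
        spec$distractor_radius^2
      dmask <- dmask & !plant
    }
    n <- spec$height * spec$width
    lab <- array(0, dim = c(spec$height, spec$width, 3))
    for (ch in 1:3) {
      base <- matrix(spec$soil_lab[ch], spec$height, spec$width)
      base[dmask] <- spec$distractor_lab[ch]
      base[plant] <- spec$plant_lab[ch]
      lab[, , ch] <- base + matrix(stats::rnorm(n, 0, spec$jitter[ch]),
                                   spec$height, spec$width)
    }
    lab[, , 1] <- pmin(pmax(lab[, , 1], 0), 100)
    lab[, , 2] <- pmin(pmax(lab[, , 2], -128), 127)
    lab[, , 3] <- pmin(pmax(lab[, , 3], -128), 127)
    list(image = lab_to_rgb(lab), mask = matrix(as.integer(plant),
                                                spec$height, spec$width),
         distractor_mask = matrix(as.integer(dmask), spec$height, spec$width),
         spec = spec)
  })
}

#' Generate predictor/response sample tables from a known model
#'
#' True predictors are drawn uniformly from per-channel ranges, the
#' response is the model evaluated at the *true* predictors plus Gaussian
#' noise, and the observed predictors are the true values plus Gaussian
#' predictor noise — the data-generating process assumed by the
#' errors-in-variables estimator. True values are retained in `true_*`
#' columns for oracle checks. Draws that fall outside a family's
#' admissible domain (e.g. a zero predictor for the reciprocal family) are
#' redrawn, with a cap on redraw attempts.
#'
#' @param model a `"canopy_model"` acting as the truth.
#' @param n number of samples.
#' @param ranges named list of `c(min, max)` per channel column (defaults:
#'   the channel's native range, shrunk away from 0 for reciprocal/power).
#' @param sigma_y response noise SD.
#' @param sigma_x named vector of predictor noise SDs (channels and, when
#'   the model uses GS, the GS column); a single number is recycled.
#' @param gs_range range for the growth-status draw.
#' @param seed RNG seed.
#' @return tibble with observed channel columns, the GS column if used,
#'   `total_N`, and `true_*` companions.
#' @export
generate_samples <- function(model, n, ranges = NULL, sigma_y = 0,
                             sigma_x = 0, gs_range = c(0.3, 0.9), seed = 1L) {
  stopifnot(inherits(model, "canopy_model"), n >= 1)
  spec <- model$spec
  chans <- spec$channels
  # typical green-vegetation channel means, not full native ranges: field
  # canopies occupy a narrow band of each channel, and the nonlinear
  # families are only well-behaved on such bands
  veg_ranges <- list(
    mean_R = c(50, 220), mean_G = c(60, 230), mean_B = c(30, 180),
    mean_H = c(0.15, 0.45), mean_S = c(0.1, 0.6), mean_I = c(0.2, 0.8),
    mean_L = c(35, 80), mean_a = c(-45, -8), mean_b = c(15, 55)
  )
  default_range <- function(ch) {
    rng <- veg_ranges[[ch]]
    if (is.null(rng)) {
      tag <- sub("^mean_", "", ch)
      rng <- CHANNEL_RANGES[[tag]]
      if (is.null(rng)) rng <- c(0, 1)
      rng <- rng + c(0.1, -0.1) * diff(rng)
    }
    if (spec$family %in% c("reciprocal", "power") && rng[1] <= 0 && rng[2] >= 0)
      rng[1] <- max(rng[1], 0.05 * diff(rng))
    rng
  }
  if (is.null(ranges)) ranges <- stats::setNames(lapply(chans, default_range), chans)
  gcol <- gs_column(spec)
  q <- length(chans) + !is.null(gcol)
  sx <- rep_len(as.numeric(sigma_x), q)

  with_local_seed(seed, {
    draw <- function() {
      X <- vapply(chans, function(ch) stats::runif(n, ranges[[ch]][1], ranges[[ch]][2]),
                  numeric(n))
      X <- matrix(X, nrow = n, dimnames = list(NULL, chans))
      gs <- if (!is.null(gcol)) stats::runif(n, gs_range[1], gs_range[2])
      list(X = X, gs = gs)
    }
    d <- draw()
    for (attempt in 1:100) {
      bad <- switch(spec$family,
        reciprocal = , power = rowSums(d$X == 0) > 0,
        logarithmic = drop(d$X %*% model$a) == 0,
        rep(FALSE, n))
      if (!any(bad)) break
      r <- draw()
      d$X[bad, ] <- r$X[bad, , drop = FALSE]
      if (!is.null(d$gs)) d$gs[bad] <- r$gs[bad]
      if (attempt == 100) stop("could not draw admissible predictors", call. = FALSE)
    }
    true_tbl <- tibble::as_tibble(d$X)
    if (!is.null(gcol)) true_tbl[[gcol]] <- d$gs
    y_true <- predict(model, true_tbl)
    obs <- true_tbl
    for (j in seq_len(ncol(obs))) obs[[j]] <- obs[[j]] + stats::rnorm(n, 0, sx[j])
    out <- obs
    out$total_N <- y_true + stats::rnorm(n, 0, sigma_y)
    names(true_tbl) <- paste0("true_", names(true_tbl))
    dplyr::bind_cols(out, true_tbl, tibble::tibble(true_N = y_true))
  })
}
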