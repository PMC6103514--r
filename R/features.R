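#' Per-sample colour and growth-status features
#'
#' Each photographed tree yields one record: the mean of every colour
#' channel over the segmented plant pixels (R, G, B on the 8-bit scale;
#' H, S, I in `[0, 1]`; L in `[0, 100]`; a, b in `[-128, 127]` — always the
#' channel's native scale, since the fitted coefficients couple to scale),
#' the two growth-status ratios, and the laboratory-measured total nitrogen
#' where available. Records are tibbles, one row per sample.
#'
#' @name features
NULL

#' Colour systems used by the prediction models
#'
#' The four three-channel systems: RGB, HSI, Lab, and the mixed "RLI"
#' system combining the R (RGB), L (Lab) and I (HSI) channels — the three
#' channels correlating most strongly with total nitrogen.
#'
#' @param name one of `"RGB"`, `"HSI"`, `"Lab"`, `"RLI"`.
#' @return character vector of the three feature-column names, in system
#'   order.
#' @export
color_system <- function(name = c("RGB", "HSI", "Lab", "RLI")) {
  name <- match.arg(name)
  switch(name,
    RGB = c("mean_R", "mean_G", "mean_B"),
    HSI = c("mean_H", "mean_S", "mean_I"),
    Lab = c("mean_L", "mean_a", "mean_b"),
    RLI = c("mean_R", "mean_L", "mean_I")
  )
}

#' Channel means over the segmented plant
#'
#' Arithmetic mean of all nine channels over foreground pixels only:
#' altering background pixels never changes the result.
#'
#' @param img original RGB array (or the masked image; background pixels
#'   are ignored either way).
#' @param mask 0/1 matrix of plant pixels (nonempty).
#' @param id optional sample identifier.
#' @return one-row tibble with `mean_R` .. `mean_b`.
#' @export
channel_means <- function(img, mask, id = NA_character_) {
  assert_rgb_image(img)
  fg <- mask != 0
  if (!any(fg)) stop("mask has no foreground pixels", call. = FALSE)
  hsi <- rgb_to_hsi(img)
  lab <- rgb_to_lab(img)
  mn <- function(sl) mean(sl[fg])
  tibble::tibble(
    id = id,
    mean_R = mn(img[, , 1]), mean_G = mn(img[, , 2]), mean_B = mn(img[, , 3]),
    mean_H = mn(hsi[, , 1]), mean_S = mn(hsi[, , 2]), mean_I = mn(hsi[, , 3]),
    mean_L = mn(lab[, , 1]), mean_a = mn(lab[, , 2]), mean_b = mn(lab[, , 3])
  )
}

#' Extract the full feature record for one image
#'
#' Runs the segmentation cascade, computes channel means over the final
#' mask and the growth-status indicators, and returns the combined record.
#'
#' @param img RGB array.
#' @param cfg a [seg_config()].
#' @inheritParams channel_means
#' @return one-row tibble: channel means, `gs_mer`, `gs_mcc`, `s_p`.
#' @export
extract_features <- function(img, cfg = seg_config(), id = NA_character_) {
  seg <- segment(img, cfg)
  gs <- growth_status(seg$mask)
  dplyr::bind_cols(
    channel_means(img, seg$mask, id = id),
    gs[, c("gs_mer", "gs_mcc", "s_p")]
  )
}

#' Predictor names of the correlation screen
#' @keywords internal
screen_predictors <- function() {
  c("mean_R", "mean_G", "mean_B", "mean_H", "mean_S", "mean_I",
    "mean_L", "mean_a", "mean_b", "gs_mcc", "gs_mer")
}

#' Pearson correlation screen against total nitrogen
#'
#' Two-tailed Pearson correlation between each predictor (nine channel
#' means and the two growth-status ratios, or any subset present) and the
#' measured total nitrogen, with significance flags at the 0.05 and 0.01
#' levels. Zero-variance predictors are flagged and excluded (r undefined).
#'
#' @param samples tibble of sample records with a `total_N` column.
#' @param predictors columns to screen (default: all standard predictors
#'   present in `samples`).
#' @return tibble with `predictor`, `r`, `p_value`, `sig_05`, `sig_01`,
#'   `excluded`, sorted by `|r|` descending.
#' @export
pearson_screen <- function(samples, predictors = NULL) {
  if (is.null(predictors))
    predictors <- intersect(screen_predictors(), names(samples))
  if (!"total_N" %in% names(samples)) stop("`samples` must contain a `total_N` column", call. = FALSE)
  y <- samples$total_N
  if (sum(stats::complete.cases(y)) < 3L) stop("need at least 3 samples with total_N", call. = FALSE)
  purrr::map_dfr(predictors, function(p) {
    x <- samples[[p]]
    if (stats::sd(x, na.rm = TRUE) == 0 || !is.finite(stats::sd(x, na.rm = TRUE))) {
      return(tibble::tibble(predictor = p, r = NA_real_, p_value = NA_real_,
                            sig_05 = NA, sig_01 = NA, excluded = TRUE))
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    tibble::tibble(predictor = p, r = unname(ct$estimate),
                   p_value = ct$p.value,
                   sig_05 = ct$p.value < 0.05, sig_01 = ct$p.value < 0.01,
                   excluded = FALSE)
  }) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)))
}

#' Channel normalizers for the exponential model family
#'
#' The exponential family divides each channel by its range
#' `x'_i = max(x_i) - min(x_i)` over the *modeling* subset; the ranges are
#' frozen into the fitted model and reused unchanged at prediction time.
#'
#' @param samples modeling-subset tibble.
#' @param channels feature-column names (e.g. from [color_system()]).
#' @return named numeric vector of ranges.
#' @export
compute_normalizers <- function(samples, channels) {
  missing <- setdiff(channels, names(samples))
  if (length(missing)) stop("missing feature columns: ", paste(missing, collapse = ", "), call. = FALSE)
  rng <- vapply(channels, function(ch) diff(range(samples[[ch]])), numeric(1))
  if (any(rng <= 0))
    stop("zero range in channel(s): ",
         paste(channels[rng <= 0], collapse = ", "),
         " — exponential normalization is undefined", call. = FALSE)
  rng
}
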