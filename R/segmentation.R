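#' Segmentation of a plant from a complex field background
#'
#' The cascade separates the target sapling from soil, weeds and darker
#' neighbouring plants using the complementary b (blue-yellow) and L
#' (lightness) channels of CIELAB:
#'
#' 1. convert to Lab, extract b and L;
#' 2. Otsu-threshold both, giving thresholds `T_b`, `T_L` and masks
#'    `I_b`, `I_L`;
#' 3. 7x7 median (majority) filter on `I_b`, mask the original image
#'    (`I_b1`);
#' 4. reconvert `I_b1` to Lab, binarize its L channel with the *original*
#'    `T_L` (`I_b2`) — this removes darker green plants that survived the
#'    b split;
#' 5. 7x7 median filter again, then erode twice and dilate twice with a
#'    radius-5 disk, and mask the original image (`I_b3`).
#'
#' @name segmentation
NULL

pad_replicate <- function(m, k) {
  n <- nrow(m); p <- ncol(m)
  ri <- c(rep(1L, k), seq_len(n), rep(n, k))
  ci <- c(rep(1L, k), seq_len(p), rep(p, k))
  m[ri, ci, drop = FALSE]
}

#' Majority (median) filter on a binary mask
#'
#' A median filter on 0/1 input is a majority vote over the window. Each
#' output pixel is foreground iff strictly more than half of the
#' `size x size` neighbourhood is foreground (an exact tie, possible only
#' for even windows, goes to background, keeping the cascade conservative).
#' Borders are handled by edge replication. Implemented with an integral
#' image, so cost is independent of window size.
#'
#' @param mask 0/1 integer matrix.
#' @param size odd window edge length (the cascade uses 7).
#' @return filtered 0/1 matrix of the same size.
#' @export
median_filter <- function(mask, size = 7L) {
  stopifnot(is.matrix(mask))
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("`size` must be odd and >= 1", call. = FALSE)
  if (size == 1L) return(mask)
  k <- (size - 1L) %/% 2L
  p <- pad_replicate(mask, k)
  # integral image with a zero top row / left column
  S <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  S[-1, -1] <- apply(apply(p, 2, cumsum), 1, cumsum) |> t()
  n <- nrow(mask); m <- ncol(mask)
  i1 <- seq_len(n); i2 <- i1 + size - 1L
  j1 <- seq_len(m); j2 <- j1 + size - 1L
  cnt <- S[i2 + 1L, j2 + 1L] - S[i1, j2 + 1L] - S[i2 + 1L, j1] + S[i1, j1]
  matrix(as.integer(2L * cnt > size * size), n, m)
}

disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# Count, for every pixel, the number of foreground pixels under the disk.
# Out-of-image area contributes `outside` (0 or 1) per offset.
disk_counts <- function(mask, offs, outside) {
  n <- nrow(mask); m <- ncol(mask); r <- max(abs(offs$dx), abs(offs$dy))
  p <- matrix(outside, n + 2L * r, m + 2L * r)
  p[r + seq_len(n), r + seq_len(m)] <- mask
  cnt <- matrix(0, n, m)
  for (i in seq_len(nrow(offs))) {
    dy <- offs$dy[i]; dx <- offs$dx[i]
    cnt <- cnt + p[r + dy + seq_len(n), r + dx + seq_len(m)]
  }
  cnt
}

#' Binary erosion with a disk structuring element
#'
#' The disk of radius `r` contains offsets with `dx^2 + dy^2 <= r^2`
#' (centre included). Pixels outside the frame count as background.
#'
#' @param mask 0/1 matrix.
#' @param radius disk radius in pixels.
#' @return eroded 0/1 matrix.
#' @export
erode_disk <- function(mask, radius = 5) {
  offs <- disk_offsets(radius)
  cnt <- disk_counts(mask, offs, outside = 0)
  matrix(as.integer(cnt == nrow(offs)), nrow(mask), ncol(mask))
}

#' Binary dilation with a disk structuring element
#'
#' @inheritParams erode_disk
#' @return dilated 0/1 matrix (clipped to the frame).
#' @export
dilate_disk <- function(mask, radius = 5) {
  offs <- disk_offsets(radius)
  cnt <- disk_counts(mask, offs, outside = 0)
  matrix(as.integer(cnt >= 1L), nrow(mask), ncol(mask))
}

#' Morphological cleaning used by the final cascade step
#'
#' Two successive erosions followed by two successive dilations with the
#' same radius-5 disk (not an opening applied twice). Removes thin spurs
#' and isolated specks left after thresholding.
#'
#' @param mask 0/1 matrix.
#' @param radius disk radius (default 5).
#' @return cleaned 0/1 matrix.
#' @export
morphological_clean <- function(mask, radius = 5) {
  m <- erode_disk(mask, radius)
  m <- erode_disk(m, radius)
  m <- dilate_disk(m, radius)
  dilate_disk(m, radius)
}

#' Zero the background of an RGB image under a mask
#'
#' The cascade's "multiply by the original image": background pixels become
#' exactly (0, 0, 0); foreground pixels keep their original values.
#'
#' @param img RGB array.
#' @param mask 0/1 matrix of matching height/width.
#' @return masked RGB array.
#' @export
apply_mask <- function(img, mask) {
  assert_rgb_image(img)
  if (!all(dim(mask) == dim(img)[1:2])) stop("mask dimensions do not match the image", call. = FALSE)
  img * array(rep(mask, 3L), dim = dim(img))
}

#' Segmentation configuration
#'
#' @param b_polarity,l_polarity which Otsu class is the plant on the b and
#'   L channels. The defaults ("high" for both) encode the field situation
#'   the cascade targets: vegetation is yellow-shifted (higher b) relative
#'   to soil, and the target plant is brighter (higher L) than neighbouring
#'   plants.
#' @param median_size window edge of the majority filter (odd).
#' @param morph_radius disk radius of the cleaning step.
#' @return a list of class `"seg_config"`.
#' @export
seg_config <- function(b_polarity = "high", l_polarity = "high",
                       median_size = 7L, morph_radius = 5) {
  structure(list(
    b_polarity = match.arg(b_polarity, c("high", "low")),
    l_polarity = match.arg(l_polarity, c("high", "low")),
    median_size = as.integer(median_size),
    morph_radius = morph_radius
  ), class = "seg_config")
}

#' Run the five-step segmentation cascade
#'
#' @param img RGB array (`h x w x 3`, components in `[0, 255]`).
#' @param cfg a [seg_config()].
#' @return an object of class `"canopy_segmentation"`: a list with the final
#'   mask (`mask`), the final masked image `I_b3`, intermediates `I_b`,
#'   `I_L`, `I_b1`, `I_b2`, and thresholds `T_b`, `T_L` on the quantized
#'   scale.
#' @examples
#' sc <- render_scene(scene_spec(width = 96, height = 96, plant_radius = 30, seed = 1))
#' seg <- segment(sc$image)
#' seg$T_b; sum(seg$mask)
#' @export
segment <- function(img, cfg = seg_config()) {
  assert_rgb_image(img)
  lab <- rgb_to_lab(img)
  ch_b <- quantize_channel(new_channel(lab[, , 3], "b"))
  ch_L <- quantize_channel(new_channel(lab[, , 1], "L"))

  step <- function(expr, what) {
    tryCatch(expr, error = function(e)
      stop(sprintf("segmentation step failed (%s): %s", what, conditionMessage(e)), call. = FALSE))
  }
  T_b <- step(otsu_threshold(ch_b), "Otsu on b channel")
  T_L <- step(otsu_threshold(ch_L), "Otsu on L channel")
  I_b <- binarize(ch_b, T_b, cfg$b_polarity)
  I_L <- binarize(ch_L, T_L, cfg$l_polarity)

  m1 <- median_filter(I_b, cfg$median_size)
  I_b1 <- apply_mask(img, m1)

  # Step 4: re-threshold the lightness of the masked image at the original
  # T_L. Zeroed background converts to L = 0; under "high" polarity it can
  # never re-enter, and under "low" polarity it is excluded explicitly.
  lab1 <- rgb_to_lab(I_b1)
  ch_L1 <- quantize_channel(new_channel(lab1[, , 1], "L"))
  I_b2 <- binarize(ch_L1, T_L, cfg$l_polarity) * m1

  m2 <- median_filter(I_b2, cfg$median_size)
  mask <- morphological_clean(m2, cfg$morph_radius)
  I_b3 <- apply_mask(img, mask)

  structure(list(mask = mask, I_b3 = I_b3, I_b = I_b, I_L = I_L,
                 I_b1 = I_b1, I_b2 = I_b2,
                 T_b = as.integer(T_b), T_L = as.integer(T_L),
                 config = cfg),
            class = "canopy_segmentation")
}

#' @export
print.canopy_segmentation <- function(x, ...) {
  cat("Canopy segmentation\n")
  cat(sprintf("  frame: %d x %d px\n", ncol(x$mask), nrow(x$mask)))
  cat(sprintf("  thresholds (quantized): T_b = %d, T_L = %d\n", x$T_b, x$T_L))
  cat(sprintf("  foreground pixels: %d (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Plot a segmentation result
#'
#' Displays the original frame, the final mask and the masked image side by
#' side as a ggplot raster panel.
#'
#' @param object a `"canopy_segmentation"`.
#' @param original optional original RGB array to show alongside.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.canopy_segmentation <- function(object, original = NULL, ...) {
  to_df <- function(img, panel) {
    d <- dim(img)
    tibble::tibble(
      x = rep(seq_len(d[2]), each = d[1]),
      y = rep(rev(seq_len(d[1])), times = d[2]),
      fill = grDevices::rgb(img[, , 1], img[, , 2], img[, , 3], maxColorValue = 255),
      panel = panel
    )
  }
  mask_img <- array(rep(object$mask * 255, 3), dim = c(dim(object$mask), 3))
  df <- dplyr::bind_rows(
    if (!is.null(original)) to_df(original, "original"),
    to_df(mask_img, "mask"),
    to_df(object$I_b3, "segmented")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
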