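#' Colour-space primitives
#'
#' Images are plain numeric arrays: an RGB image is a `height x width x 3`
#' array with components on the 8-bit scale `[0, 255]`; a channel image is a
#' `height x width` matrix carrying a `"channel"` attribute naming one of
#' `R, G, B, H, S, I, L, a, b`. These primitives (conversion, channel
#' extraction, 8-bit quantization, Otsu thresholding, binarization) are the
#' building blocks of the segmentation cascade.
#'
#' @name colorspace
NULL

CHANNEL_RANGES <- list(
  R = c(0, 255), G = c(0, 255), B = c(0, 255),
  H = c(0, 1), S = c(0, 1), I = c(0, 1),
  L = c(0, 100), a = c(-128, 127), b = c(-128, 127)
)

assert_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be a height x width x 3 array", arg), call. = FALSE)
  d <- dim(img)
  if (d[1] < 1L || d[2] < 1L)
    stop(sprintf("`%s` has zero-sized dimensions", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` components must lie in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

new_channel <- function(values, channel) {
  stopifnot(is.matrix(values), channel %in% names(CHANNEL_RANGES))
  structure(values, channel = channel)
}

channel_tag <- function(ch) {
  tag <- attr(ch, "channel")
  if (is.null(tag)) stop("channel image lacks a `channel` attribute", call. = FALSE)
  tag
}

#' Convert an RGB image to CIELAB
#'
#' Applies sRGB gamma decoding and the CIE 1976 L*a*b* transform under the
#' D65 reference white (the standard assumption for uncalibrated camera
#' output). L is in `[0, 100]`; the opponent channels a (green-red) and
#' b (blue-yellow) in roughly `[-128, 127]`.
#'
#' @param img numeric `h x w x 3` array, components in `[0, 255]`.
#' @return `h x w x 3` array with L, a, b slices.
#' @examples
#' img <- array(255, dim = c(2, 2, 3))
#' rgb_to_lab(img)[1, 1, ]  # white -> L = 100, a = b = 0
#' @export
rgb_to_lab <- function(img) {
  assert_rgb_image(img)
  d <- dim(img)
  flat <- matrix(img, ncol = 3L) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab",
                                 to.ref.white = "D65")
  array(lab, dim = d)
}

#' Convert CIELAB values to an RGB image
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut values are clipped to `[0, 255]`.
#' Used by the synthetic scene renderer, which paints scenes in Lab.
#'
#' @param lab numeric `h x w x 3` array of L, a, b values.
#' @return RGB array on the 8-bit scale.
#' @export
lab_to_rgb <- function(lab) {
  stopifnot(is.array(lab), length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  d <- dim(lab)
  flat <- grDevices::convertColor(matrix(lab, ncol = 3L), from = "Lab",
                                  to = "sRGB", from.ref.white = "D65")
  array(pmin(pmax(flat, 0), 1) * 255, dim = d)
}

#' Convert an RGB image to HSI
#'
#' Hue-saturation-intensity with the arccos hue formulation:
#' `I = (R+G+B)/(3*255)`, `S = 1 - 3*min(R,G,B)/(R+G+B)` and hue from
#' `acos(((R-G)+(R-B))/2 / sqrt((R-G)^2 + (R-B)(G-B)))`, reflected when
#' `B > G` and normalized to `[0, 1)`. Achromatic pixels (R = G = B) take
#' H = 0 and S = 0 by convention.
#'
#' @inheritParams rgb_to_lab
#' @return `h x w x 3` array with H, S, I slices, each in `[0, 1]`.
#' @export
rgb_to_hsi <- function(img) {
  assert_rgb_image(img)
  d <- dim(img)
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  s <- R + G + B
  I <- s / (3 * 255)
  mn <- pmin(R, G, B)
  S <- ifelse(s > 0, 1 - 3 * mn / s, 0)
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  achrom <- den < .Machine$double.eps^0.5
  theta <- acos(pmin(pmax(ifelse(achrom, 1, num / ifelse(achrom, 1, den)), -1), 1))
  H <- ifelse(B > G, 2 * pi - theta, theta) / (2 * pi)
  H[achrom] <- 0
  H[H >= 1] <- 0
  array(c(H, S, I), dim = d)
}

#' Extract a single channel from an image
#'
#' @param img RGB array (for R/G/B) — converted internally for H/S/I/L/a/b.
#' @param channel one of `"R","G","B","H","S","I","L","a","b"`.
#' @return channel matrix on its native scale, tagged with the channel name.
#' @export
extract_channel <- function(img, channel) {
  channel <- match.arg(channel, names(CHANNEL_RANGES))
  src <- switch(channel,
    R = , G = , B = img,
    H = , S = , I = rgb_to_hsi(img),
    L = , a = , b = rgb_to_lab(img)
  )
  idx <- switch(channel, R = 1L, G = 2L, B = 3L, H = 1L, S = 2L, I = 3L,
                L = 1L, a = 2L, b = 3L)
  new_channel(src[, , idx], channel)
}

#' Quantize a channel image to the 8-bit scale
#'
#' Affinely maps the channel's native range (L: `[0,100]`; a, b:
#' `[-128,127]`; H, S, I: `[0,1]`; R, G, B: `[0,255]`) to integers in
#' `[0, 255]`, so Otsu can operate on a 256-bin histogram. The mapping is
#' fixed per channel tag, so thresholds stay interpretable on either scale.
#'
#' @param ch tagged channel matrix from [extract_channel()].
#' @return integer-valued channel matrix in `[0, 255]`, same tag.
#' @export
quantize_channel <- function(ch) {
  tag <- channel_tag(ch)
  rng <- CHANNEL_RANGES[[tag]]
  q <- round((unclass(ch) - rng[1]) / (rng[2] - rng[1]) * 255)
  new_channel(pmin(pmax(q, 0), 255), tag)
}

#' Otsu threshold of a quantized channel
#'
#' Exhaustive 256-bin Otsu: picks the threshold `t` maximizing the
#' between-class variance of the split `value <= t` versus `value > t`.
#' Ties are broken by the smallest maximizing threshold. A constant image
#' has no valid split and is an error.
#'
#' @param ch integer-valued channel matrix in `[0, 255]`
#'   (see [quantize_channel()]).
#' @return threshold on the quantized scale, with the channel tag attached.
#' @export
otsu_threshold <- function(ch) {
  v <- as.vector(unclass(ch))
  if (any(v < 0 | v > 255)) stop("otsu_threshold() expects a quantized channel in [0, 255]", call. = FALSE)
  h <- tabulate(as.integer(round(v)) + 1L, nbins = 256L)
  n <- sum(h)
  if (sum(h > 0) < 2L) stop("constant image: Otsu has no valid split", call. = FALSE)
  lev <- 0:255
  w0 <- cumsum(h)                 # count of pixels <= t, t = 0..255
  m0 <- cumsum(h * lev)           # intensity mass <= t
  mu <- m0[256] / n
  w0p <- w0 / n
  # between-class variance for t = 0..254; undefined where a class is empty
  sb <- (mu * w0p - m0 / n)^2 / (w0p * (1 - w0p))
  sb <- sb[1:255]
  sb[!is.finite(sb)] <- -Inf
  t <- which.max(sb) - 1L         # smallest maximizer (which.max takes first)
  structure(t, channel = channel_tag(ch))
}

#' Binarize a channel image at a threshold
#'
#' Foreground is `value > t` under polarity `"high"` and `value <= t` under
#' polarity `"low"`; the two polarities partition the pixels, with exact-`t`
#' pixels always in the low class. Which Otsu class is the plant depends on
#' the channel, so polarity is an explicit argument.
#'
#' @param ch quantized channel matrix.
#' @param t threshold on the same quantized scale (from [otsu_threshold()]).
#' @param polarity `"high"` or `"low"`.
#' @return binary mask matrix (integer 0/1).
#' @export
binarize <- function(ch, t, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  tt <- as.numeric(t)
  if (tt < 0 || tt > 255) stop("threshold must lie on the quantized scale [0, 255]", call. = FALSE)
  v <- unclass(ch)
  m <- if (polarity == "high") v > tt else v <= tt
  matrix(as.integer(m), nrow = nrow(v))
}
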