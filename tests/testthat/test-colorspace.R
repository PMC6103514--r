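test_that("Lab conversion matches the sRGB/D65 reference formulas", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))

  white <- rgb_to_lab(px(255, 255, 255))[1, 1, ]
  expect_equal(white[1], 100, tolerance = 1e-6)
  expect_lt(abs(white[2]), 0.5)
  expect_lt(abs(white[3]), 0.5)

  expect_equal(rgb_to_lab(px(0, 0, 0))[1, 1, ], c(0, 0, 0), tolerance = 1e-8)

  # mid gray: step-by-step reference conversion (sRGB decoding, luminance,
  # CIE cube-root lightness); a and b vanish for neutrals
  g <- 119 / 255
  lin <- ((g + 0.055) / 1.055)^2.4
  fy <- lin^(1 / 3)          # lin > (6/29)^3, cube-root branch
  L_ref <- 116 * fy - 16
  gray <- rgb_to_lab(px(119, 119, 119))[1, 1, ]
  expect_equal(gray[1], L_ref, tolerance = 0.05)
  expect_lt(abs(gray[2]), 1e-6)
  expect_lt(abs(gray[3]), 1e-6)
})

test_that("HSI conversion follows the arccos hue formulation", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))

  gray <- rgb_to_hsi(px(100, 100, 100))[1, 1, ]
  expect_equal(gray, c(0, 0, 100 / 255), tolerance = 1e-12)

  red <- rgb_to_hsi(px(255, 0, 0))[1, 1, ]
  expect_equal(red, c(0, 1, 1 / 3), tolerance = 1e-12)

  # pure green: theta = acos(-1/2) = 2*pi/3, B <= G keeps it unreflected
  green <- rgb_to_hsi(px(0, 255, 0))[1, 1, ]
  expect_equal(green[1], (2 * pi / 3) / (2 * pi), tolerance = 1e-12)
  expect_equal(green[2], 1, tolerance = 1e-12)
  expect_equal(green[3], 1 / 3, tolerance = 1e-12)

  # blue must land in the reflected half: H = 2/3
  blue <- rgb_to_hsi(px(0, 0, 255))[1, 1, ]
  expect_equal(blue[1], 2 / 3, tolerance = 1e-12)
})

test_that("conversions are pixel-wise (permuting pixels permutes outputs)", {
  set.seed(5)
  img <- array(sample(0:255, 3 * 24, replace = TRUE), dim = c(4, 6, 3))
  flipped <- img[4:1, 6:1, , drop = FALSE]
  for (fun in list(rgb_to_lab, rgb_to_hsi)) {
    expect_equal(fun(flipped), fun(img)[4:1, 6:1, , drop = FALSE],
                 tolerance = 1e-12)
  }
})

test_that("quantization maps native ranges onto [0, 255] monotonically", {
  ch <- function(v, tag) structure(matrix(v, 1), channel = tag)
  expect_equal(as.vector(quantize_channel(ch(100, "L"))), 255)
  expect_equal(as.vector(quantize_channel(ch(0, "L"))), 0)
  expect_equal(as.vector(quantize_channel(ch(50, "L"))), 128)  # round(127.5)
  expect_equal(as.vector(quantize_channel(ch(127, "b"))), 255)
  expect_equal(as.vector(quantize_channel(ch(-128, "b"))), 0)

  x <- sort(runif(50, -128, 127))
  q <- as.vector(quantize_channel(ch(x, "a")))
  expect_true(all(diff(q) >= 0))
})

test_that("Otsu equals the exhaustive 256-candidate oracle", {
  ch <- function(v) structure(matrix(v, nrow = 1), channel = "L")

  # perfectly bimodal: the two levels land in different classes
  v <- c(rep(10, 50), rep(200, 50))
  t <- otsu_threshold(ch(v))
  expect_gte(as.integer(t), 10)
  expect_lt(as.integer(t), 200)

  # four-pixel case: classes {0,0} vs {255,255} under "foreground > t"
  t4 <- otsu_threshold(ch(c(0, 0, 255, 255)))
  expect_equal(as.integer(t4), oracle_otsu(c(0, 0, 255, 255)))
  m <- binarize(ch(c(0, 0, 255, 255)), t4, "high")
  expect_equal(as.vector(m), c(0L, 0L, 1L, 1L))

  set.seed(42)
  for (i in 1:25) {
    v <- sample(0:255, 60, replace = TRUE)
    expect_equal(as.integer(otsu_threshold(ch(v))), oracle_otsu(v))
  }

  expect_error(otsu_threshold(ch(rep(7, 10))), "constant")
})

test_that("binarize respects polarity and partitions at the threshold", {
  ch <- structure(matrix(c(0, 128, 128, 255), 2), channel = "L")
  expect_equal(sum(binarize(ch, 0, "high")), 3)
  expect_equal(sum(binarize(ch, 255, "high")), 0)

  chk <- structure(matrix(rep(c(0, 255), 8), 4), channel = "L")
  m <- binarize(chk, 128, "high")
  expect_equal(m, matrix(as.integer(chk == 255), 4))

  # exact-threshold pixels belong to the low class only
  hi <- binarize(ch, 128, "high")
  lo <- binarize(ch, 128, "low")
  expect_equal(hi + lo, matrix(1L, 2, 2))
  expect_equal(lo[ch == 128], c(1L, 1L))
})

test_that("degenerate images are rejected with informative errors", {
  expect_error(rgb_to_lab(array(0, dim = c(0, 4, 3))), "zero-sized")
  expect_error(rgb_to_lab(matrix(0, 3, 3)), "array")
  expect_error(rgb_to_lab(array(300, dim = c(2, 2, 3))), "\\[0, 255\\]")
})
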