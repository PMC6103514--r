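test_that("the published optimal model evaluates exactly at the origin", {
  m <- reference_model()
  rec <- tibble::tibble(mean_L = 0, mean_a = 0, mean_b = 0, gs_mcc = 0)
  # exp(0) = 1 forces y = a0 + b0 = 237.374 - 4.274
  expect_identical(predict(m, rec), 237.374 - 4.274)
  expect_equal(predict(m, rec), 233.100)
})

test_that("each family evaluates its printed expression", {
  set.seed(8)
  rec <- tibble::tibble(mean_L = 62.3, mean_a = -21.4, mean_b = 37.9,
                        gs_mcc = 0.55, gs_mer = 0.4)
  a <- c(0.7, -1.3, 0.4); b0 <- 2.5; b1 <- 5; a0 <- 1.8
  nz <- c(45, 30, 40)
  x <- c(rec$mean_L, rec$mean_a, rec$mean_b)
  ags <- b0 + b1 * rec$gs_mcc

  expected <- list(
    linear = ags + sum(a * x),
    reciprocal = ags + sum(a / x),
    power = ags + a0 * prod(abs(x)^a),
    logarithmic = ags + a0 * log(abs(sum(a * x))),
    exponential = ags + a0 * exp(sum(a * x / nz))
  )
  for (fam in names(expected)) {
    m <- canopy_model(model_spec(fam, "Lab", "MCC"), a = a, b0 = b0,
                      a0 = if (fam %in% c("power", "logarithmic", "exponential")) a0,
                      b1 = b1,
                      normalizers = if (fam == "exponential") nz)
    expect_equal(predict(m, rec), expected[[fam]], tolerance = 1e-12,
                 info = fam)
  }
})

test_that("a zero GS coefficient collapses the GS variants", {
  set.seed(14)
  rec <- tibble::tibble(mean_L = runif(10, 40, 80), mean_a = runif(10, -40, -10),
                        mean_b = runif(10, 15, 55), gs_mcc = runif(10, 0.3, 0.9),
                        gs_mer = runif(10, 0.3, 0.9))
  a <- c(-1, 0.5, 0.2)
  for (fam in c("linear", "exponential")) {
    args <- list(a = a, b0 = 3,
                 a0 = if (fam == "exponential") 2,
                 normalizers = if (fam == "exponential") c(45, 30, 40))
    none <- do.call(canopy_model, c(list(model_spec(fam, "Lab", "none")), args))
    mcc <- do.call(canopy_model, c(list(model_spec(fam, "Lab", "MCC")),
                                   args, list(b1 = 0)))
    mer <- do.call(canopy_model, c(list(model_spec(fam, "Lab", "MER")),
                                   args, list(b1 = 0)))
    expect_equal(predict(mcc, rec), predict(none, rec), tolerance = 1e-12)
    expect_equal(predict(mer, rec), predict(none, rec), tolerance = 1e-12)
  }
})

test_that("predict is locally smooth away from singular points", {
  rec0 <- tibble::tibble(mean_L = 60, mean_a = -25, mean_b = 35, gs_mcc = 0.6)
  for (fam in c("reciprocal", "power", "logarithmic", "exponential")) {
    m <- canopy_model(model_spec(fam, "Lab", "MCC"), a = c(-1.2, 0.8, 0.3),
                      b0 = 1, a0 = if (fam != "reciprocal") 2, b1 = 4,
                      normalizers = if (fam == "exponential") c(45, 30, 40))
    h <- 1e-6
    for (ch in c("mean_L", "mean_a", "mean_b")) {
      up <- rec0; up[[ch]] <- up[[ch]] + h
      dn <- rec0; dn[[ch]] <- dn[[ch]] - h
      second_diff <- predict(m, up) - 2 * predict(m, rec0) + predict(m, dn)
      expect_lt(abs(second_diff), 1e-6)
    }
  }
})

test_that("domain violations raise errors", {
  rec <- tibble::tibble(mean_L = 0, mean_a = 5, mean_b = 5, gs_mcc = 0.5)
  recip <- canopy_model(model_spec("reciprocal", "Lab", "MCC"),
                        a = c(1, 1, 1), b0 = 0, b1 = 0)
  expect_error(predict(recip, rec), "reciprocal")

  pw <- canopy_model(model_spec("power", "Lab", "MCC"),
                     a = c(-1, 1, 1), b0 = 0, a0 = 1, b1 = 0)
  expect_error(predict(pw, rec), "power")

  lg <- canopy_model(model_spec("logarithmic", "Lab", "MCC"),
                     a = c(1, -1, 0), b0 = 0, a0 = 1, b1 = 0)
  expect_error(predict(lg, tibble::tibble(mean_L = 5, mean_a = 5, mean_b = 1,
                                          gs_mcc = 0.5)), "logarithmic")
})

test_that("the model grid enumerates 5 x 4 x 3 specifications", {
  g <- model_grid()
  expect_equal(nrow(g), 60)
  expect_equal(nrow(model_grid(family = "exponential")), 12)
  expect_equal(nrow(model_grid(gs_variant = "MCC",
                               family = c("reciprocal", "power",
                                          "logarithmic", "exponential"))), 16)
  expect_s3_class(g$spec[[1]], "canopy_model_spec")
})

test_that("models round-trip through JSON", {
  m <- reference_model(normalizers = c(45.2, 30.1, 39.7))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(m2$normalizers, m$normalizers, tolerance = 1e-12)
  expect_equal(m2$spec$family, "exponential")
  rec <- tibble::tibble(mean_L = 60, mean_a = -25, mean_b = 35, gs_mcc = 0.6)
  expect_equal(predict(m2, rec), predict(m, rec), tolerance = 1e-12)
})
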