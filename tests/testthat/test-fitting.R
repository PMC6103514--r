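test_that("noiseless data is interpolated exactly by least squares", {
  for (fam in c("linear", "reciprocal", "power", "exponential")) {
    tr <- truth_for(fam)
    d <- generate_samples(tr, 60, sigma_y = 0, sigma_x = 0, seed = 7)
    f <- fit_lsm(tr$spec, d, normalizers = tr$normalizers)
    expect_lt(max(abs(coef(f$model) - coef(tr))), 1e-6)
    expect_lt(f$objective, 1e-10)
  }
  # the logarithmic family is identifiable only up to a scaling of the
  # channel coefficients (absorbed by a0 and b0): compare the normalized
  # direction and the predictions
  tr <- truth_for("logarithmic")
  d <- generate_samples(tr, 60, sigma_y = 0, sigma_x = 0, seed = 7)
  f <- fit_lsm(tr$spec, d, normalizers = tr$normalizers)
  expect_lt(f$objective, 1e-10)
  dir_fit <- f$model$a / sqrt(sum(f$model$a^2)) * sign(f$model$a[1])
  dir_tr <- tr$a / sqrt(sum(tr$a^2)) * sign(tr$a[1])
  expect_lt(max(abs(dir_fit - dir_tr)), 1e-6)
  expect_lt(max(abs(predict(f$model, d) - d$true_N)), 1e-6)
})

test_that("linear least squares matches the normal equations closed form", {
  set.seed(19)
  tr <- truth_for("linear")
  d <- generate_samples(tr, 48, sigma_y = 0.4, sigma_x = 0, seed = 3)
  f <- fit_lsm(tr$spec, d)
  X <- cbind(1, d$mean_L, d$mean_a, d$mean_b, d$gs_mcc)
  beta <- solve(crossprod(X), crossprod(X, d$total_N))
  expect_equal(unname(coef(f$model)[c("b0", "a1", "a2", "a3", "b1")]),
               as.numeric(beta), tolerance = 1e-9)
})

test_that("a constant response yields zero slopes and b0 at the mean", {
  set.seed(4)
  d <- tibble::tibble(mean_L = runif(30, 40, 80), mean_a = runif(30, -40, -10),
                      mean_b = runif(30, 15, 55), total_N = 7)
  f <- fit_lsm(model_spec("linear", "Lab", "none"), d)
  expect_lt(max(abs(f$model$a)), 1e-10)
  expect_equal(f$model$b0, 7, tolerance = 1e-8)
})

test_that("noisy exponential data recovers the generating coefficients", {
  tr <- truth_for("exponential")
  rng <- list(mean_L = c(50, 75), mean_a = c(-35, -15), mean_b = c(25, 45))
  d <- generate_samples(tr, 200, ranges = rng, sigma_y = 0.3, sigma_x = 0,
                        seed = 23)
  f <- fit_lsm(tr$spec, d, normalizers = tr$normalizers)
  expect_true(f$converged)
  rel <- abs(coef(f$model) - coef(tr)) / pmax(abs(coef(tr)), 1)
  expect_lt(max(rel), 0.2)
  expect_equal(sign(coef(f$model)), sign(coef(tr)))
})

test_that("EIV reduces to least squares when predictors are error-free", {
  tr <- truth_for("exponential")
  rng <- list(mean_L = c(50, 75), mean_a = c(-35, -15), mean_b = c(25, 45))
  d <- generate_samples(tr, 60, ranges = rng, sigma_y = 0.4, sigma_x = 0,
                        seed = 31)
  fl <- fit_lsm(tr$spec, d, normalizers = tr$normalizers)
  fe <- fit_eiv(tr$spec, d, normalizers = tr$normalizers,
                sigma = eiv_sigma(0.16, c(0, 0, 0, 0)))
  expect_lt(max(abs(coef(fe$model) - coef(fl$model)) /
                  pmax(abs(coef(fl$model)), 1)), 1e-4)
  # latent adjustments vanish in this limit
  Z <- as.matrix(d[, c("mean_L", "mean_a", "mean_b", "gs_mcc")])
  expect_lt(max(abs(fe$latent - Z)), 1e-4)
})

test_that("EIV equals closed-form Deming regression on straight-line data", {
  sp <- model_spec("linear", "custom", "none", channels = "mean_L")
  set.seed(47)
  for (i in 1:40) {
    n <- sample(15:50, 1)
    s <- runif(1, 0.2, 1)
    xt <- runif(n, 0, 10)
    x <- xt + rnorm(n, 0, s)
    y <- 0.5 + 1.7 * xt + rnorm(n, 0, s)
    fe <- fit_eiv(sp, tibble::tibble(mean_L = x, total_N = y),
                  sigma = eiv_sigma(s^2, c(mean_L = s^2)))
    expect_lt(abs(fe$model$a - oracle_deming_slope(x, y)), 1e-6)
  }
})

test_that("the EIV objective trace is monotone non-increasing", {
  tr <- truth_for("exponential")
  rng <- list(mean_L = c(50, 75), mean_a = c(-35, -15), mean_b = c(25, 45))
  d <- generate_samples(tr, 60, ranges = rng, sigma_y = 0.5,
                        sigma_x = c(1.8, 0.8, 1, 0.03), seed = 57)
  fe <- fit_eiv(tr$spec, d, normalizers = tr$normalizers,
                sigma = eiv_sigma(0.25, c(1.8, 0.8, 1, 0.03)^2))
  expect_true(all(diff(fe$trace) <= 1e-8 * (1 + abs(fe$trace[-1]))))
})

test_that("the default error-variance heuristic follows the accuracy bounds", {
  set.seed(61)
  d <- tibble::tibble(mean_L = runif(12, 45, 55),
                      mean_a = runif(12, -40, -10),
                      mean_b = runif(12, 15, 55),
                      gs_mcc = runif(12, 0.4, 0.8),
                      total_N = runif(12, 5, 20))
  sg <- estimate_sigma(d, model_spec("linear", "Lab", "MCC"))
  # 3% of the mean channel level (mean_L ~ 50 -> sigma ~ 1.5)
  expect_equal(sqrt(sg$x[["mean_L"]]), 0.03 * mean(d$mean_L), tolerance = 1e-6)
  expect_equal(sqrt(sg$x[["gs_mcc"]]), 0.05 * mean(d$gs_mcc), tolerance = 1e-6)
  expect_gt(sg$y, 0)

  ov <- eiv_sigma(2, c(mean_L = 1, mean_a = 1, mean_b = 1, gs_mcc = 0.01))
  fe <- fit_eiv(model_spec("linear", "Lab", "MCC"), d, sigma = ov)
  expect_identical(fe$sigma, ov)

  # perfect fit: response variance floored at a positive constant
  d2 <- tibble::tibble(mean_L = seq(40, 80, length.out = 12),
                       mean_a = runif(12, -40, -10),
                       mean_b = runif(12, 15, 55))
  d2$total_N <- 2 + 0.1 * d2$mean_L
  sg2 <- estimate_sigma(d2, model_spec("linear", "custom", "none",
                                       channels = "mean_L"))
  expect_gte(sg2$y, 1e-8)
})

test_that("EIV is less biased than least squares under predictor noise", {
  tr <- truth_for("exponential")
  rng <- list(mean_L = c(50, 75), mean_a = c(-35, -15), mean_b = c(25, 45))
  sx <- c(1.8, 0.8, 1, 0.03); sy <- 0.5
  sig <- eiv_sigma(sy^2, sx^2)
  reps <- lapply(1:12, function(r) {
    d <- generate_samples(tr, 60, ranges = rng, sigma_y = sy, sigma_x = sx,
                          seed = 400 + r)
    fl <- fit_lsm(tr$spec, d, normalizers = tr$normalizers,
                  control = fit_control(n_starts = 2))
    fe <- fit_eiv(tr$spec, d, normalizers = tr$normalizers, sigma = sig,
                  control = fit_control(n_starts = 2, eiv_max_iter = 5))
    rbind(lsm = coef(fl$model), eiv = coef(fe$model))
  })
  tru <- coef(tr)
  med_lsm <- apply(sapply(reps, function(m) abs(m["lsm", ] - tru)), 1, median)
  med_eiv <- apply(sapply(reps, function(m) abs(m["eiv", ] - tru)), 1, median)
  expect_lt(mean(med_eiv / pmax(abs(tru), 1)), mean(med_lsm / pmax(abs(tru), 1)))
})

test_that("low-noise data recovers coefficient signs across families", {
  ok <- 0L; total <- 0L
  for (fam in c("linear", "reciprocal", "power", "exponential")) {
    tr <- truth_for(fam)
    rng <- if (fam == "exponential")
      list(mean_L = c(50, 75), mean_a = c(-35, -15), mean_b = c(25, 45))
    for (r in 1:5) {
      d <- generate_samples(tr, 80, ranges = rng, sigma_y = 0.05, seed = 700 + r)
      # occasional iteration-limit flags are acceptable here; the sign
      # criterion below is what is under test
      f <- suppressWarnings(fit_lsm(tr$spec, d, normalizers = tr$normalizers,
                                    control = fit_control(n_starts = 3)))
      total <- total + 1L
      if (all(sign(coef(f$model)) == sign(coef(tr)))) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.9)
})
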