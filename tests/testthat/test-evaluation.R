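# Construct an observed/predicted pair realizing prescribed e_bar and
# delta2 exactly (n samples; standardized residual pattern).
pairs_with <- function(e_bar, delta2, n = 24) {
  z <- scale(seq_len(n))[, 1]                 # mean 0, sum(z^2) = n - 1
  s2 <- delta2 - n * e_bar^2 / (n - 1)
  stopifnot(s2 > 0)
  r <- e_bar + sqrt(s2) * z
  y <- seq(10, 30, length.out = n)
  list(observed = y, predicted = y - r)
}

test_that("perfect predictions give the degenerate report", {
  y <- c(3, 7, 11, 2, 9)
  st <- eval_stats(y, y)
  expect_equal(st$e_bar, 0)
  expect_equal(st$delta2, 0)
  expect_equal(st$mse, 0)
  expect_equal(st$r_squared, 1)
})

test_that("statistics match a direct hand computation on five pairs", {
  y <- c(10, 12, 15, 9, 14)
  yp <- c(11, 11.5, 14, 10, 12)
  st <- eval_stats(y, yp)
  r <- y - yp                                  # -1, 0.5, 1, -1, 2
  expect_equal(st$e_bar, mean(r), tolerance = 1e-12)
  expect_equal(st$delta2, sum(r^2) / 4, tolerance = 1e-12)
  expect_equal(st$mse, mean(r)^2 + sum(r^2) / 4, tolerance = 1e-12)
  expect_equal(st$rmse, sqrt(st$mse), tolerance = 1e-12)
  expect_equal(st$r_squared, 1 - sum(r^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
})

test_that("rmse^2 - delta2 equals e_bar^2 on arbitrary reports", {
  set.seed(44)
  for (i in 1:20) {
    y <- rnorm(15, 10, 3); yp <- y + rnorm(15, 0.3, 1)
    st <- eval_stats(y, yp)
    expect_equal(st$rmse^2 - st$delta2, st$e_bar^2, tolerance = 1e-12)
  }
})

test_that("published validation statistics reproduce the printed error value", {
  # the optimal Lab exponential model's least-squares validation row
  p <- pairs_with(-0.2632, 3.7496)
  st <- eval_stats(p$observed, p$predicted)
  expect_equal(st$e_bar, -0.2632, tolerance = 1e-10)
  expect_equal(st$delta2, 3.7496, tolerance = 1e-10)
  expect_equal(round(st$rmse, 4), 1.9542)
})

test_that("R-squared is invariant to a common affine shift", {
  set.seed(15)
  y <- rnorm(20, 12, 4); yp <- y + rnorm(20, 0, 1.5)
  s1 <- eval_stats(y, yp)
  s2 <- eval_stats(3 * y + 5, 3 * yp + 5)
  expect_equal(s1$r_squared, s2$r_squared, tolerance = 1e-12)
})

test_that("evaluate_model wires predictions through to the statistics", {
  tr <- canopy_model(model_spec("linear", "Lab", "none"),
                     a = c(0.1, -0.2, 0.05), b0 = 2)
  d <- generate_samples(tr, 30, sigma_y = 0.5, seed = 5)
  rep <- evaluate_model(tr, d)
  expect_equal(rep$n, 30)
  direct <- eval_stats(d$total_N, predict(tr, d))
  expect_equal(rep, direct, tolerance = 1e-12)
})

test_that("a candidate dominating every criterion ranks first", {
  cand <- tibble::tibble(
    model = c("good", "mid", "bad"),
    mod_r_squared = c(0.95, 0.9, 0.85),
    mod_e_bar = c(-0.1, -0.2, 0.3),
    val_r_squared = c(0.93, 0.88, 0.8),
    val_e_bar = c(0.05, -0.15, 0.25),
    val_delta2 = c(1, 2, 3),
    val_rmse = c(1, 1.4, 1.8)
  )
  rt <- rank_models(cand)
  expect_equal(rt$model[rt$order == 1], "good")
  expect_equal(rt$score[rt$model == "good"], 6)
})

test_that("identical candidates tie and keep input order", {
  cand <- tibble::tibble(
    model = c("a", "b"),
    mod_r_squared = 0.9, mod_e_bar = -0.2, val_r_squared = 0.88,
    val_e_bar = -0.1, val_delta2 = 2, val_rmse = 1.5
  )
  rt <- rank_models(cand)
  expect_true(all(rt$tied))
  expect_equal(rt$model[rt$order == 1], "a")
  expect_error(rank_models(cand[, -3]), "missing criterion")
})

test_that("the seven published candidates place the Lab exponential near the top", {
  # modeling columns from the EIV regression table; validation columns
  # from the EIV block of the validation table
  cand <- tibble::tibble(
    model = c("reciprocal-Lab", "power-RGB", "power-Lab", "log-RGB",
              "exp-RGB", "exp-Lab", "exp-RLI"),
    mod_r_squared = c(0.906, 0.915, 0.911, 0.905, 0.916, 0.935, 0.908),
    mod_e_bar = c(-0.219, -0.221, -0.151, -0.231, -0.212, -0.266, -0.312),
    val_e_bar = c(-0.2039, -0.1593, -0.0791, -0.1843, -0.1736, -0.2494, -0.3194),
    val_delta2 = c(4.2941, 4.0193, 4.3941, 4.5932, 4.0183, 3.5931, 4.0384),
    val_rmse = c(2.0822, 2.0111, 2.0977, 2.1511, 2.0121, 1.9119, 2.0348),
    val_r_squared = c(0.8956, 0.8991, 0.8957, 0.8817, 0.9063, 0.9110, 0.8931)
  )
  rt <- rank_models(cand)
  expect_lte(rt$order[rt$model == "exp-Lab"], 2)
})
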