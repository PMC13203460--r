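# Metrics and agreement statistics against hand/brute-force oracles.

test_that("regression metrics match hand arithmetic", {
  y <- c(50, 60, 70); yhat <- c(52, 59, 74)
  m <- regression_metrics(y, yhat)
  expect_equal(m$mae, 7 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(7), tolerance = 1e-12)
  expect_equal(m$r2, 1 - 21 / 200, tolerance = 1e-12)
  expect_equal(m$mape, 100 * mean(c(2 / 50, 1 / 60, 4 / 70)),
               tolerance = 1e-12)

  p <- regression_metrics(y, y)
  expect_equal(c(p$mae, p$rmse, p$mape), c(0, 0, 0))
  expect_equal(p$r2, 1)

  null_m <- regression_metrics(y, rep(mean(y), 3))
  expect_equal(null_m$r2, 0)

  expect_error(regression_metrics(y, yhat[1:2]), class = "ff_argument_error")
  expect_error(regression_metrics(c(0, 1), c(1, 1)),
               class = "ff_argument_error")
})

test_that("MAE never exceeds RMSE, with equality only for equal errors", {
  set.seed(40)
  for (i in 1:20) {
    y <- rnorm(15, 60, 5); yhat <- y + rnorm(15)
    m <- regression_metrics(y, yhat)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
  eq <- regression_metrics(c(10, 20, 30), c(12, 18, 32))  # all |e| = 2
  expect_equal(eq$mae, eq$rmse)
})

test_that("Lin's CCC matches the population-moment formula", {
  y <- c(1, 2, 3)
  expect_equal(lin_ccc(y, y), 1)
  expect_equal(lin_ccc(y, y + 1), 4 / 7, tolerance = 1e-12)
  expect_lt(lin_ccc(y, -y + 4), 0)
  # symmetric in its arguments, and bounded by |r|
  set.seed(41)
  a <- rnorm(30, 60, 8); b <- a + rnorm(30, 1, 2)
  expect_equal(lin_ccc(a, b), lin_ccc(b, a), tolerance = 1e-12)
  expect_lte(abs(lin_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  # equals Pearson r when means and variances agree exactly
  x1 <- c(1, 2, 3, 4); x2 <- c(2, 1, 4, 3)
  expect_equal(lin_ccc(x1, x2), cor(x1, x2), tolerance = 1e-12)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 2, 3)), class = "ff_argument_error")
})

test_that("Bland-Altman statistics match hand arithmetic", {
  y <- c(50, 60)
  ba0 <- bland_altman(y, y)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  ba1 <- bland_altman(c(10, 20), c(11, 19))  # d = (+1, -1)
  expect_equal(ba1$bias, 0)
  expect_equal(ba1$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba1$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba1$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)

  # uniform shift: bias equals the shift, zero dispersion
  y3 <- c(48, 60, 75, 88)
  ba2 <- bland_altman(y3, y3 + 0.12)
  expect_equal(ba2$bias, 0.12, tolerance = 1e-12)
  expect_equal(ba2$sd_diff, 0)
  # the invariant linking limits to bias and SD
  set.seed(42)
  yy <- rnorm(50, 60, 8); hh <- yy + rnorm(50, 0.5, 1)
  ba3 <- bland_altman(yy, hh)
  expect_equal(ba3$loa_low, ba3$bias - 1.96 * ba3$sd_diff)
  expect_equal(ba3$loa_high, ba3$bias + 1.96 * ba3$sd_diff)
  expect_error(bland_altman(1, 2), class = "ff_argument_error")
})

test_that("Bland-Altman limits cover about 95% of normal differences", {
  set.seed(43)
  n <- 10000
  y <- rnorm(n, 60, 8)
  yhat <- y + rnorm(n, 0.2, 1.5)
  ba <- bland_altman(y, yhat)
  d <- yhat - y
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gte(cover, 0.94)
  expect_lte(cover, 0.96)
})

test_that("exact Wilcoxon signed-rank agrees with sign-flip enumeration", {
  brute_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    p_le <- mean(Ws <= W + 1e-9)
    p_ge <- mean(Ws >= W - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  fixtures <- list(
    c(1.2, -0.4, 2.5, 0.3, -1.8, 0.9),
    c(0.5, 0.5, -0.5, 1.5, 2.5, -2.5),        # heavy ties
    c(1, 2, 3, 4, 5, 6),                       # all positive
    c(-0.2, 0.7, 1.1, -1.1, 0.4, -0.6, 2.2),
    c(1, -1, 2, -2, 3, -3, 4, -4, 5, 5))
  for (d in fixtures) {
    got <- flockfusion:::wilcoxon_signed_rank(d)
    expect_equal(got$p_value, brute_p(d), tolerance = 1e-12,
                 label = paste("fixture", paste(d, collapse = ",")))
  }
  # agrees with the classical exact test when there are no ties
  set.seed(44)
  d <- round(rnorm(9, 0.3, 1), 3)
  ours <- flockfusion:::wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$statistic, unname(ref$statistic))
})

test_that("paired model comparison returns both tests with sane edge cases", {
  e <- c(1, 2, 3, 4, 5, 6)
  same <- compare_models_errors(e, e)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$t_p, 1)
  expect_true(is.na(same$wilcoxon_p))

  # errA stochastically larger by construction -> small p in that direction
  set.seed(45)
  errB <- abs(rnorm(40, 0, 1))
  errA <- errB + abs(rnorm(40, 0.8, 0.3))
  res <- compare_models_errors(errA, errB)
  expect_lt(res$t_p, 0.05)
  expect_lt(res$wilcoxon_p, 0.05)
  expect_gt(res$mean_diff, 0)
  expect_equal(flockfusion:::wilcoxon_signed_rank(errA - errB)$method,
               "normal approximation")
  expect_error(compare_models_errors(1:3, 1:3), class = "ff_argument_error")
})
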