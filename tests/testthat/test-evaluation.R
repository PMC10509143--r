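test_that("metric formulas match their definitions on frozen cases", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 2), c(1, 1)), 1)
  y <- c(10, 20, 30)
  expect_equal(mae(y, y + 7), 7)   # constant shift moves MAE by |c|
  expect_equal(mape(c(100), c(90)), 10)
  expect_equal(mape(y, y), 0)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_lt(r2(c(1, 2, 3), c(3, 1, 2)), 0)  # worse than the mean predictor
})

test_that("metric guards reject invalid inputs", {
  expect_error(mae(1:3, 1:2), "length mismatch")
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mape(c(5, 0, 3), c(5, 1, 3)), "index: 2")
  expect_error(r2(c(4, 4, 4), c(1, 2, 3)), "total sum of squares")
})

test_that("metrics agree with loop oracles on random vectors", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(2:60, 1)
    y <- runif(n, 10, 500)
    p <- y + rnorm(n, sd = 20)
    expect_equal(mae(y, p), mae_oracle(y, p), tolerance = 1e-12)
    expect_equal(mape(y, p), mape_oracle(y, p), tolerance = 1e-12)
    expect_equal(r2(y, p), r2_oracle(y, p), tolerance = 1e-12)
  }
})

test_that("translation invariance holds for MAE and Bland-Altman, not R^2", {
  set.seed(72)
  y <- runif(50, 50, 300)
  p <- y + rnorm(50, sd = 15)
  expect_equal(mae(y + 100, p + 100), mae(y, p))
  a1 <- bland_altman(p, y)
  a2 <- bland_altman(p + 100, y + 100)
  expect_equal(a2$bias, a1$bias)
  expect_equal(a2$loa_lower, a1$loa_lower)
  expect_equal(a2$loa_upper, a1$loa_upper)
})

test_that("degenerate equal differences give zero-width limits", {
  y <- c(10, 20, 30, 40)
  a <- bland_altman(y + 5, y)
  expect_equal(a$bias, 5)
  expect_equal(a$sd_diff, 0)
  expect_equal(a$loa_lower, 5)
  expect_equal(a$loa_upper, 5)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("parametric limits are symmetric about the bias", {
  set.seed(73)
  for (i in 1:10) {
    y <- runif(30, 10, 400)
    p <- y + rnorm(30, sd = 12)
    a <- bland_altman(p, y)
    expect_equal(a$loa_lower + a$loa_upper, 2 * a$bias)
    expect_true(a$loa_lower <= a$bias && a$bias <= a$loa_upper)
    expect_true(a$ci_bias[1] <= a$bias && a$bias <= a$ci_bias[2])
  }
})

test_that("Bland-Altman recovers the generating normal parameters", {
  set.seed(74)
  d <- rnorm(10000, mean = 5, sd = 10)
  a <- bland_altman(d, numeric(10000))
  expect_equal(a$bias, 5, tolerance = 0.3 / 5)
  expect_lt(abs(a$loa_lower - (-14.6)), 0.5)
  expect_lt(abs(a$loa_upper - 24.6), 0.5)
})

test_that("percentile limits approach the parametric ones for normal data", {
  set.seed(75)
  d <- rnorm(20000, mean = 2, sd = 8)
  par <- bland_altman(d, numeric(20000))
  np <- bland_altman(d, numeric(20000), loa_mode = "percentile")
  expect_equal(np$loa_lower, par$loa_lower, tolerance = 0.3 / abs(par$loa_lower))
  expect_equal(np$loa_upper, par$loa_upper, tolerance = 0.3 / par$loa_upper)
})

test_that("CI dialects share the bias interval and differ on the LOA", {
  set.seed(76)
  y <- runif(100, 50, 300)
  p <- y + rnorm(100, sd = 15)
  pooled <- bland_altman(p, y)
  textbook <- bland_altman(p, y, ci_mode = "textbook")
  expect_equal(pooled$ci_bias, textbook$ci_bias)
  hw_pooled <- diff(pooled$ci_loa_upper) / 2
  hw_text <- diff(textbook$ci_loa_upper) / 2
  expect_equal(hw_text / hw_pooled, sqrt(3))
  # pooled dialect: all three intervals share one half-width
  expect_equal(diff(pooled$ci_bias), diff(pooled$ci_loa_lower))
})

test_that("either agreement limit determines its mirror", {
  expect_equal(ba_mirror_limit(1.343, 32.5), -29.814)
  expect_equal(ba_mirror_limit(1.343, -29.814), 32.5)
  a <- bland_altman(c(1, 4, 9, 2), c(0, 2, 5, 1))
  expect_equal(ba_mirror_limit(a$bias, a$loa_upper), a$loa_lower)
})

test_that("pairwise comparison table reports improvements both ways", {
  m <- list(
    fe = structure(list(mae = 27.34, mape = 21.9, r2 = 0.96, n = 256),
                   class = "metric_set"),
    rn = structure(list(mae = 14.66, mape = 10.7, r2 = 0.99, n = 256),
                   class = "metric_set"))
  tab <- compare_models(m)
  fe_rn <- tab[tab$baseline == "fe" & tab$model == "rn", ]
  expect_equal(fe_rn$mae_improvement_mg, 12.68)
  expect_equal(fe_rn$mape_improvement_pct, 11.2)
  expect_equal(fe_rn$r2_improvement, 0.03)
  self <- tab[tab$baseline == "fe" & tab$model == "fe", ]
  expect_equal(self$mae_improvement_mg, 0)
  expect_equal(self$mape_improvement_pct, 0)
  expect_equal(self$r2_improvement, 0)
  expect_error(compare_models(m["fe"]), "at least two")
})
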