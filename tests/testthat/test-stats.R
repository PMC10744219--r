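test_that("Pearson regression matches hand-computed values", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_regression(x, x)$r, 1)
  expect_equal(pearson_regression(x, -x)$r, -1)
  # covariance 1, sd_x = sd_y = sqrt(5/3): r = 3/5
  expect_equal(pearson_regression(x, c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson_regression(c(1, 1, 1), c(1, 2, 3)),
               "undefined correlation")
  expect_error(pearson_regression(1:2, 1:2), "at least 3")
})

test_that("Pearson r is invariant to positive affine transforms", {
  set.seed(42)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  r0 <- pearson_regression(x, y)$r
  expect_equal(pearson_regression(3 * x + 10, 0.2 * y - 4)$r, r0)
})

test_that("Bland-Altman bias and limits of agreement", {
  x0 <- c(10, 20, 30)
  ba <- bland_altman(x0, x0)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))

  # d = (2, -2, 3): bias 1, sd sqrt(7)
  ba2 <- bland_altman(c(0, 0, 0), c(2, -2, 3))
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd_diff, sqrt(7))
  expect_equal(ba2$loa_low, 1 - 1.96 * sqrt(7))
  expect_equal(ba2$loa_high, 1 + 1.96 * sqrt(7))
  expect_equal(round(c(ba2$loa_low, ba2$loa_high), 2), c(-4.19, 6.19))

  # constant offset: bias c, zero-width limits
  ba3 <- bland_altman(x0, x0 + 5)
  expect_equal(c(ba3$bias, ba3$loa_low, ba3$loa_high), c(5, 5, 5))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("agreement summary combines correlation and bias", {
  set.seed(1)
  x <- rnorm(20, 30, 5)
  agr <- interobserver_agreement(x, x + 2)
  expect_equal(agr$pearson_r, 1)
  expect_equal(agr$bias, 2)
  expect_true(agr$loa_low <= agr$bias && agr$bias <= agr$loa_high)
})

test_that("adjusted OLS: exact fit, orthogonal adjustment, rank errors", {
  x <- 1:20
  fit <- suppressWarnings(adjusted_ols(2 * x, x))  # "essentially perfect fit"
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "predictor"], 2)
  expect_equal(co$ci_high[co$term == "predictor"] -
               co$ci_low[co$term == "predictor"], 0)

  # covariate orthogonal to the predictor leaves its coefficient unchanged
  set.seed(5)
  pred <- rep(c(-1, 1), 25)
  covar <- rep(c(-1, -1, 1, 1), length.out = 50)  # orthogonal to pred
  y <- 3 * pred + rnorm(50)
  b_un <- coef(adjusted_ols(y, pred))[["predictor"]]
  b_adj <- coef(adjusted_ols(y, pred, data.frame(c1 = covar)))[["predictor"]]
  expect_equal(b_adj, b_un, tolerance = 1e-10)

  expect_error(adjusted_ols(y, pred, data.frame(dup = pred)),
               "collinear.*dup")
})

test_that("adjusted OLS recovers a known volume-index slope", {
  set.seed(99)
  n <- 500
  lvesvi <- rnorm(n, 28, 8)
  age <- rnorm(n, 50, 17)
  sex <- rbinom(n, 1, 0.5)
  ind <- 46 - 0.46 * lvesvi + 0.01 * age + rnorm(n, sd = 1)
  fit <- adjusted_ols(ind, lvesvi, data.frame(age = age, sex = sex))
  co <- fit$coefficients[fit$coefficients$term == "predictor", ]
  expect_true(co$ci_low <= -0.46 && -0.46 <= co$ci_high)
  expect_equal(co$estimate, -0.46, tolerance = 0.05)
})

test_that("cohort tables stratify with means, SDs and both interval types", {
  # two subjects (30, 34) in one cell: mean 32, sd = 2 sqrt(2)
  d <- data.frame(subject_id = c("a", "b"), age = c(25, 28),
                  segment = 1L, ind_pct = c(30, 34))
  tab <- cohort_table(d)
  expect_equal(tab$mean_pct, 32)
  expect_equal(tab$sd_pct, round(sqrt(8), 1))
  expect_equal(tab$n, 2L)

  # identical subjects: zero SD, zero-width intervals
  d2 <- data.frame(subject_id = c("a", "b", "c"), age = 35,
                   segment = 1L, ind_pct = 30)
  t2 <- cohort_table(d2)
  expect_equal(t2$sd_pct, 0)
  expect_equal(t2$ci_low, t2$ci_high)
  expect_equal(t2$ref_low, t2$ref_high)

  # singleton cells are omitted with a warning
  d3 <- rbind(d, data.frame(subject_id = "z", age = 71, segment = 1L,
                            ind_pct = 40))
  expect_warning(t3 <- cohort_table(d3), "fewer than 2")
  expect_equal(nrow(t3), 1)
})
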