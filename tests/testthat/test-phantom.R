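test_that("phantom spec validates contraction fractions", {
  expect_error(phantom_spec(s = 1.2), "would cross the center")
  expect_error(phantom_spec(s = 0.95), "lie in")
  expect_error(phantom_spec(s = -0.6), "lie in")
  expect_error(phantom_spec(s = rep(0.3, 5)), "length-17")
  expect_error(phantom_spec(n_points = 10), "at least 20")
})

test_that("paired phantom is an exact construction oracle", {
  ph <- generate_phantom(phantom_spec(s = 0.33, n_points = 120))
  expect_equal(unname(ph$truth$bullseye$seg_pct), rep(33, 17),
               tolerance = 1e-12)
  fit <- inward_displacement(ph$contours)
  expect_equal(coef(fit), ph$truth$bullseye$seg_pct, tolerance = 1e-12)

  # zero contraction: akinesis everywhere, no volume change, no strain
  ph0 <- generate_phantom(phantom_spec(s = 0, n_points = 80))
  expect_equal(unname(ph0$truth$bullseye$seg_pct), rep(0, 17))
  expect_equal(ph0$truth$ef_pct, 0, tolerance = 1e-9)
  expect_equal(ph0$truth$gls_pct, 0)

  # a dyskinetic segment yields negative InD
  s <- rep(0.3, 17); s[4] <- -0.1
  phd <- generate_phantom(phantom_spec(s = s, n_points = 160))
  fitd <- suppressWarnings(inward_displacement(phd$contours))
  expect_lt(coef(fitd)[["4"]], 0)
})

test_that("a locally elevated contraction fraction is recovered in its segment", {
  s <- rep(0.3, 17); s[10] <- 0.484
  ph <- generate_phantom(phantom_spec(s = s, n_points = 200))
  fit <- inward_displacement(ph$contours)
  expect_equal(coef(fit), ph$truth$bullseye$seg_pct, tolerance = 1e-12)
  # boundary smoothing pulls the segment mean slightly toward its neighbours
  expect_equal(coef(fit)[["10"]], 48.4, tolerance = 0.8)
  expect_equal(unname(coef(fit)[-10]), rep(30, 16), tolerance = 0.5)
})

test_that("resampled mode stays within 1 point of construction truth", {
  ph <- generate_phantom(phantom_spec(s = 0.33, n_points = 200,
                                      mode = "resampled"))
  expect_false(ph$contours$paired)
  fit <- inward_displacement(ph$contours)
  expect_lt(max(abs(coef(fit) - ph$truth$bullseye$seg_pct)), 1)
})

test_that("phantom volumes agree between disk summation and the fine oracle", {
  ph <- generate_phantom(phantom_spec(s = 0.33, n_points = 200))
  fit <- inward_displacement(ph$contours)
  expect_lt(abs(fit$metrics$ef_pct - ph$truth$ef_pct), 1.5)
  expect_lt(abs(fit$metrics$edv_ml - ph$truth$edv_ml) / ph$truth$edv_ml, 0.015)
  expect_lt(abs(fit$metrics$esv_ml - ph$truth$esv_ml) / ph$truth$esv_ml, 0.015)
})

test_that("phantom output is deterministic per seed", {
  p1 <- generate_phantom(phantom_spec(noise_sd_mm = 0.8, seed = 12))
  p2 <- generate_phantom(phantom_spec(noise_sd_mm = 0.8, seed = 12))
  p3 <- generate_phantom(phantom_spec(noise_sd_mm = 0.8, seed = 13))
  expect_identical(p1$contours, p2$contours)
  expect_false(identical(p1$contours, p3$contours))
  expect_equal(p1$spec$seed, 12L)
})

test_that("annular descent shifts the base and lowers basal InD purity", {
  ph <- generate_phantom(phantom_spec(s = 0.33, annular_descent_mm = 5,
                                      n_points = 120))
  es <- ph$clean$contours[["4CH ES"]]$points
  expect_gt(min(es[c(1, nrow(es)), 2]), 0)  # annulus moved toward the apex
  # truth still equals the pipeline on paired input
  fit <- inward_displacement(ph$contours)
  expect_equal(coef(fit), ph$truth$bullseye$seg_pct, tolerance = 1e-12)
})

test_that("simulated observers are deterministic and unbiased at zero jitter", {
  ph <- generate_phantom(phantom_spec(s = 0.33, n_points = 100))
  same <- simulate_observers(ph$contours, jitter_sd_mm = 0)
  expect_identical(same, ph$contours)
  o1 <- simulate_observers(ph$contours, jitter_sd_mm = 1, seed = 4)
  o2 <- simulate_observers(ph$contours, jitter_sd_mm = 1, seed = 4)
  expect_identical(o1, o2)

  fit <- inward_displacement(ph$contours)
  ba <- bland_altman(unname(coef(fit)), unname(coef(fit)))
  expect_equal(ba$bias, 0)
})

test_that("observer jitter keeps segmental InD strongly correlated", {
  set.seed(21)
  orig <- perturbed <- numeric(0)
  for (i in 1:12) {
    s <- pmin(pmax(rnorm(17, ind_reference()$mean_pct / 100,
                         ind_reference()$sd_pct / 100), -0.4), 0.9)
    ph <- generate_phantom(phantom_spec(s = s, n_points = 120, seed = i))
    fit <- inward_displacement(ph$contours)
    obs2 <- simulate_observers(ph$contours, jitter_sd_mm = 1, seed = 1000 + i)
    fit2 <- inward_displacement(obs2)
    orig <- c(orig, unname(coef(fit)))
    perturbed <- c(perturbed, unname(coef(fit2)))
  }
  expect_gt(pearson_regression(orig, perturbed)$r, 0.7)
})
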