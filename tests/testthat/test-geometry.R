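test_that("fit_axis recovers the annular midpoint and apex", {
  ax <- fit_axis(half_ellipse(r = 20, L = 90, n = 101))
  expect_equal(ax$base_mid, c(0, 0))
  expect_equal(ax$apex, c(0, 90))
  expect_equal(ax$length_mm, 90)

  # translation equivariance
  ct <- half_ellipse(r = 20, L = 90, n = 101)
  ax2 <- fit_axis(ct$points + matrix(c(5, 5), nrow(ct$points), 2, byrow = TRUE))
  expect_equal(ax2$base_mid, c(5, 5))
  expect_equal(ax2$apex, c(5, 95))
  expect_equal(ax2$length_mm, 90)

  # farthest point defines the apex: annuli (-20,0),(20,0), far point (10,80)
  p <- rbind(c(-20, 0), cbind(seq(-19, 9, length.out = 25),
                              seq(5, 75, length.out = 25)),
             c(10, 80), cbind(seq(11, 19, length.out = 8),
                              seq(70, 5, length.out = 8)), c(20, 0))
  ax3 <- fit_axis(p)
  expect_equal(ax3$length_mm, sqrt(100 + 6400))
  expect_equal(ax3$apex, c(10, 80))

  expect_error(fit_axis(matrix(1, 30, 2)), "zero-length axis")
})

test_that("longitudinal fraction projects onto the axis and clamps", {
  ax <- fit_axis(half_ellipse(r = 20, L = 90, n = 101))
  expect_equal(longitudinal_fraction(ax$base_mid, ax), 0)
  expect_equal(longitudinal_fraction(ax$apex, ax), 1)
  # orthogonal offset ignored
  expect_equal(longitudinal_fraction(c(15, 45), ax), 0.5)
  # projections beyond the ends are clamped
  expect_equal(longitudinal_fraction(c(0, -10), ax), 0)
  expect_equal(longitudinal_fraction(c(0, 100), ax), 1)
})

test_that("contraction centre interpolates from half to two thirds of the axis", {
  ax <- fit_axis(half_ellipse(r = 20, L = 90, n = 101))
  expect_equal(contraction_center(0, ax)[1, ], c(0, 45))
  expect_equal(contraction_center(1, ax)[1, ], c(0, 60))
  expect_equal(contraction_center(0.5, ax)[1, ], c(0, 52.5))  # 7L/12

  d3 <- center_rule(mode = "discrete3")
  expect_equal(contraction_center(c(0.2, 0.5, 0.9), ax, d3)[, 2],
               90 * c(1 / 2, 7 / 12, 2 / 3))

  # monotone non-decreasing in f (continuous mode)
  f <- sort(runif(50))
  g <- contraction_center(f, ax)[, 2]
  expect_true(all(diff(g) >= 0))

  expect_error(center_rule(f_base = 0.7, f_apex = 0.6), "invalid center rule")
  expect_error(center_rule(f_base = 0), "invalid center rule")
})

test_that("arc-length resampling is equally spaced and similarity-invariant", {
  # straight 100 mm polyline, 5 samples -> arc 0, 25, 50, 75, 100
  p <- cbind(c(0, 10, 40, 100), 0)
  rs <- resample_polyline(p, 5)
  expect_equal(rs[, 1], c(0, 25, 50, 75, 100))

  ed <- half_ellipse(n = 41)
  rs1 <- resample_polyline(ed$points, 30)
  rs2 <- resample_polyline(2.5 * ed$points, 30)
  expect_equal(rs2, 2.5 * rs1)
})

test_that("correspond_points pairs identical contours with zero displacement", {
  ed <- half_ellipse(n = 57)
  es <- lax_contour(ed$points, ed$view, "ES")
  for (n in c(20L, 50L, 121L)) {
    pr <- correspond_points(ed, es, n)
    expect_equal(pr$ed, pr$es)
  }
  other <- half_ellipse(n = 57, view = "2CH", phase = "ES")
  expect_error(correspond_points(ed, other, 50), "mismatched views")
  expect_error(correspond_points(ed, es, 10), "at least 20")
})

test_that("point-wise inward displacement follows the sign contract", {
  # halfway to the centre
  r <- point_inward_displacement(c(40, 0), c(20, 0), c(0, 0))
  expect_equal(r$ind_mm, 20)
  expect_equal(r$ind_pct, 50)
  # akinesis
  r0 <- point_inward_displacement(c(40, 0), c(40, 0), c(0, 0))
  expect_equal(r0$ind_pct, 0)
  # dyskinesis: outward motion is negative
  rn <- point_inward_displacement(c(40, 0), c(50, 0), c(0, 0))
  expect_equal(rn$ind_mm, -10)
  expect_equal(rn$ind_pct, -25)
  # the theoretical limit: the point reaches the centreline
  r100 <- point_inward_displacement(c(40, 0), c(0, 0), c(0, 0))
  expect_equal(r100$ind_pct, 100)
  expect_error(point_inward_displacement(c(0, 0), c(1, 1), c(0, 0)),
               "coincides with center")
})

test_that("InD is antisymmetric under reflecting ES through ED", {
  set.seed(7)
  for (i in 1:20) {
    p_ed <- runif(2, -40, 40)
    ctr <- runif(2, -10, 10)
    if (sqrt(sum((p_ed - ctr)^2)) < 1) next
    step <- runif(1, -0.5, 0.9) * (ctr - p_ed)
    fwd <- point_inward_displacement(p_ed, p_ed + step, ctr)
    bwd <- point_inward_displacement(p_ed, p_ed - step, ctr)
    expect_equal(fwd$ind_pct, -bwd$ind_pct)
  }
})

test_that("InD is invariant under rigid motions of all inputs", {
  set.seed(11)
  ed <- half_ellipse(n = 81)
  ax <- fit_axis(ed)
  f <- longitudinal_fraction(ed$points, ax)
  ctr <- contraction_center(f, ax)
  es <- ed$points + 0.3 * (ctr - ed$points)
  base <- point_inward_displacement(ed$points, es, ctr)
  for (i in 1:5) {
    a <- runif(1, 0, 2 * pi)
    sh <- runif(2, -50, 50)
    ed_t <- transform_points(ed$points, a, sh)
    ax_t <- fit_axis(ed_t)
    ctr_t <- contraction_center(longitudinal_fraction(ed_t, ax_t), ax_t)
    got <- point_inward_displacement(ed_t, transform_points(es, a, sh), ctr_t)
    expect_equal(got$ind_pct, base$ind_pct, tolerance = 1e-10)
    expect_equal(got$ind_mm, base$ind_mm, tolerance = 1e-10)
  }
})

test_that("moving every ED point fraction s toward its centre gives 100 s", {
  ed <- half_ellipse(n = 101)
  ax <- fit_axis(ed)
  ctr <- contraction_center(longitudinal_fraction(ed$points, ax), ax)
  for (s in c(-0.2, 0, 0.1, 0.33, 0.5, 0.9)) {
    es <- ed$points + s * (ctr - ed$points)
    got <- point_inward_displacement(ed$points, es, ctr)
    expect_equal(got$ind_pct, rep(100 * s, nrow(ed$points)), tolerance = 1e-12)
  }
})
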