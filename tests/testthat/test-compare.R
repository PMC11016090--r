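test_that("depth of focus measures superthreshold extent with interpolated crossings", {
  # rectangle: exactly at threshold on the edges, 2.0 D wide
  f <- seq(-1, 3, by = 0.1)
  v <- ifelse(f > 0 & f < 2, 0.5, 0)
  v[abs(f - 0) < 1e-9] <- 0.12
  v[abs(f - 2) < 1e-9] <- 0.12
  d <- depth_of_focus(tf_curve(f, v))
  expect_equal(d$total_D, 2.0, tolerance = 1e-9)
  expect_equal(d$largest_D, 2.0, tolerance = 1e-9)

  low <- depth_of_focus(tf_curve(f, rep(0.05, length(f))))
  expect_equal(low$total_D, 0)
  expect_identical(nrow(low$intervals), 0L)

  # bimodal: above threshold on [-0.2, 0.4] and [2.6, 3.2]
  f2 <- seq(-1, 4, by = 0.1)
  inside <- (f2 > -0.2 & f2 < 0.4) | (f2 > 2.6 & f2 < 3.2)
  v2 <- ifelse(inside, 0.62, 0.02)
  v2[sapply(f2, function(x) any(abs(x - c(-0.2, 0.4, 2.6, 3.2)) < 1e-9))] <- 0.12
  d2 <- depth_of_focus(tf_curve(f2, v2))
  expect_equal(d2$total_D, 1.2, tolerance = 1e-9)
  expect_equal(d2$largest_D, 0.6, tolerance = 1e-9)
  expect_identical(nrow(d2$intervals), 2L)
})

test_that("depth of focus is monotone non-increasing in the threshold", {
  set.seed(5)
  f <- seq(-2, 4, by = 0.05)
  v <- pmin(pmax(0.3 * exp(-(f - 0.5)^2) + 0.25 * exp(-(f - 2)^2 / 0.3), 0), 1)
  tf <- tf_curve(f, v)
  ths <- seq(0.05, 0.4, by = 0.05)
  dofs <- vapply(ths, function(t) depth_of_focus(tf, t)$total_D, 0)
  expect_true(all(diff(dofs) <= 1e-12))
})

test_that("partial correlation matches the regression-residual oracle to 1e-12", {
  set.seed(101)
  for (i in 1:20) {
    z <- rnorm(6)
    x <- 0.5 * z + rnorm(6)
    y <- -0.3 * z + rnorm(6)
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(partial_correlation(x, y, z), oracle, tolerance = 1e-12)
  }
})

test_that("partial correlation handles identities, symmetry and degeneracy", {
  z <- c(1, 2, 3, 5, 8, 13)
  x <- c(0.3, -1, 2, 0.7, 1.1, -0.2)
  expect_equal(partial_correlation(x, x, z), 1, tolerance = 1e-12)
  y <- 2 * x + z
  expect_equal(partial_correlation(x, y, z), partial_correlation(y, x, z))
  # affine invariance
  expect_equal(partial_correlation(3 * x - 1, y, z),
               partial_correlation(x, y, z), tolerance = 1e-12)
  expect_equal(partial_correlation(x, y, -2 * z + 5),
               partial_correlation(x, y, z), tolerance = 1e-12)
  expect_error(partial_correlation(x, z, z), "collinear")
  expect_error(partial_correlation(x, y, rep(1, 6)), "zero variance")
  expect_error(partial_correlation(x[1:3], x[1:3] + 1, z[1:3]), "at least 4")
})

test_that("curve RMSE matches hand arithmetic and the triangle inequality", {
  f <- c(0, 0.5, 1)
  a <- tf_curve(f, c(0, 0.1, 0.2))
  b <- tf_curve(f, c(0.1, 0.1, 0.1))
  expect_equal(curve_rmse(a, b), sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(curve_rmse(a, a), 0)
  cst <- tf_curve(f, c(0.05, 0.15, 0.25))
  expect_equal(curve_rmse(a, cst), 0.05, tolerance = 1e-12)

  set.seed(3)
  x <- tf_curve(f, runif(3)); y <- tf_curve(f, runif(3)); w <- tf_curve(f, runif(3))
  expect_lte(curve_rmse(x, w), curve_rmse(x, y) + curve_rmse(y, w) + 1e-12)

  far <- tf_curve(c(5, 5.5), c(0.1, 0.1))
  expect_error(curve_rmse(a, far), "overlap")
})

test_that("curve comparison reports partial r, RMSE and mean difference", {
  f <- seq(-2, 2, by = 0.5)
  x <- tf_curve(f, plogis(-f))               # simulated
  y <- tf_curve(f, plogis(-f) + 0.02)        # reference, constant offset
  cmp <- compare_curves(x, y)
  expect_gt(cmp$partial_r, 0.999)
  expect_equal(cmp$rmse, 0.02, tolerance = 1e-9)
  expect_equal(cmp$mean_diff, 0.02, tolerance = 1e-9)
  expect_identical(cmp$n, length(f))
})

test_that("pupil diameters snap to the 0.5 mm simulation grid", {
  measured <- c(3.90, 4.40, 2.80, 2.90, 3.10, 3.50, 3.50, 3.80)
  matched  <- c(4.00, 4.50, 3.00, 3.00, 3.00, 3.50, 3.50, 4.00)
  expect_equal(match_pupil_step(measured), matched)
  # exact midpoints round up
  expect_equal(match_pupil_step(c(3.25, 3.75)), c(3.5, 4.0))
  expect_error(match_pupil_step(0), "0, 8")
  expect_error(match_pupil_step(8.5), "0, 8")
})
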