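test_that("profile construction enforces the measurement-domain invariants", {
  p <- power_profile(c(0, 1), c(-2.0, -1.5))
  expect_s3_class(p, "power_profile")
  expect_length(p$radii_mm, 2L)
  expect_error(power_profile(c(0, 1, 1, 2), c(1, 1, 1, 1)), "strictly increasing")
  expect_error(power_profile(c(0, 2, 4), c(1, 1, 1)), "3.0 mm")
  expect_error(power_profile(c(0, 1), c(1, NA)), "finite")
  expect_error(power_profile(c(0, 1, 2), c(1, 1)), "equal length")
})

test_that("moving average matches the hand-computed truncated-window oracle", {
  p <- power_profile(0:6 * 0.4, c(1, 2, 3, 4, 5, 6, 7))
  s <- smooth_profile(p, window = 5)
  # interior: centered 5-sample means; ends: truncated to available samples
  expect_equal(s$powers_D, c(2, 2.5, 3, 4, 5, 5.5, 6))
  expect_identical(s$radii_mm, p$radii_mm)

  const <- smooth_profile(power_profile(0:5 * 0.5, rep(2, 6)), 5)
  expect_equal(const$powers_D, rep(2, 6))

  expect_error(smooth_profile(p, window = 4), "odd")
  expect_error(smooth_profile(p, window = 9), "length")
})

test_that("smoothing never extends the value range", {
  set.seed(7)
  for (i in 1:10) {
    p <- power_profile(seq(0, 3, length.out = 41), rnorm(41, 0, 1))
    s <- smooth_profile(p, window = 5)
    expect_gte(min(s$powers_D), min(p$powers_D) - 1e-12)
    expect_lte(max(s$powers_D), max(p$powers_D) + 1e-12)
  }
})

test_that("repetition averaging gives the pointwise mean and SD", {
  r <- seq(0, 3, by = 0.5)
  mk <- function(v, rep) power_profile(r, rep(v, length(r)), repetition = rep)
  avg <- average_repetitions(list(mk(1.0, 1), mk(2.0, 2)))
  expect_equal(avg$powers_D, rep(1.5, length(r)))
  expect_equal(avg$sd_D, rep(sqrt(0.5), length(r)), tolerance = 1e-12)
  expect_identical(avg$repetition, 0L)

  same <- average_repetitions(list(mk(1.2, 1), mk(1.2, 2), mk(1.2, 3)))
  expect_equal(same$powers_D, rep(1.2, length(r)))
  expect_equal(same$sd_D, rep(0, length(r)))

  single <- average_repetitions(list(mk(0.7, 1)))
  expect_equal(single$powers_D, rep(0.7, length(r)))

  bad <- power_profile(r, rep(1, length(r)), family = "other")
  expect_error(average_repetitions(list(mk(1, 1), bad)), "metadata")
})

test_that("relative profile subtracts the distance power and is not idempotent", {
  p <- power_profile(c(0, 1, 2), c(-1.25, -1.5, -2.0), distance_power_D = -2.0)
  rel <- relative_profile(p)
  expect_equal(rel$powers_D, c(0.75, 0.5, 0))
  expect_equal(relative_profile(rel)$powers_D, c(2.75, 2.5, 2))

  mono <- power_profile(c(0, 1, 2), rep(-3, 3), distance_power_D = -3)
  expect_equal(relative_profile(mono)$powers_D, rep(0, 3))
})

test_that("averaging repetitions commutes with distance-power subtraction", {
  r <- seq(0, 3, by = 0.25)
  set.seed(11)
  reps <- lapply(1:3, function(k)
    power_profile(r, 1.5 * exp(-r) + rnorm(length(r), 0, 0.05),
                  distance_power_D = -2.5, repetition = k))
  a <- relative_profile(average_repetitions(reps))
  b <- average_repetitions(lapply(reps, relative_profile))
  expect_equal(a$powers_D, b$powers_D, tolerance = 1e-14)
})

test_that("design averaging interpolates to the union grid on shared support", {
  p1 <- power_profile(c(0, 1, 2), c(0, 1, 2))
  p2 <- power_profile(c(0, 0.5, 1, 1.5, 2), c(1, 1, 1, 1, 1))
  d <- average_design(list(p1, p2))
  expect_equal(d$radii_mm, c(0, 0.5, 1, 1.5, 2))
  # p1 interpolated: 0, 0.5, 1, 1.5, 2; mean with constant 1
  expect_equal(d$rel_powers_D, (c(0, 0.5, 1, 1.5, 2) + 1) / 2)
  expect_identical(d$n_distance_powers, 2L)

  two <- average_design(list(constant_to_profile(0.5), constant_to_profile(1.5)))
  expect_equal(two$rel_powers_D, rep(1.0, 7))

  expect_error(average_design(list()), "at least one")
  far <- power_profile(c(2.5, 3), c(1, 1))
  near <- power_profile(c(0, 0.5), c(1, 1))
  expect_error(average_design(list(far, near)), "overlap")
})

test_that("triplicate noise at 0.08 D stays below the 0.10 D repeatability bound after smoothing", {
  spec <- design_spec("aspheric_center_near", add_D = 1.5,
                      params = list(half_radius_mm = 1.5), distance_power_D = -2)
  reps <- simulate_measurement(spec, n_reps = 3, noise_sd_D = 0.08, seed = 21)
  avg <- average_repetitions(lapply(reps, smooth_profile))
  expect_gte(mean(avg$sd_D < 0.10), 0.95)
})
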