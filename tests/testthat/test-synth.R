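test_that("archetype evaluation matches its closed forms", {
  r <- seq(0, 3, by = 0.25)
  mono <- evaluate_design(design_spec("monofocal"), r)
  expect_equal(mono$rel_powers_D, rep(0, length(r)))

  bif <- design_spec("pure_bifocal", add_D = 3,
                     params = list(zone_radii_mm = 1.5, zone_powers_D = c(3, 0)))
  bv <- evaluate_design(bif, c(1.0, 2.0))
  expect_equal(bv$rel_powers_D, c(3, 0))

  asph <- design_spec("aspheric_center_near", add_D = 2,
                      params = list(half_radius_mm = 1.5))
  av <- evaluate_design(asph, 1.5)
  expect_equal(av$rel_powers_D, 2 * exp(-1), tolerance = 1e-12)

  expect_error(evaluate_design(mono_spec <- design_spec("monofocal"), c(-0.1, 1)),
               "within")
  expect_error(design_spec("pure_bifocal", add_D = 3,
                           params = list(zone_radii_mm = c(1, 2),
                                         zone_powers_D = c(3, 1, 0))),
               "exactly 2 zones")
  expect_error(design_spec("concentric_rings", add_D = 1,
                           params = list(zone_radii_mm = c(2, 1),
                                         zone_powers_D = c(1, 0, 1))),
               "strictly increasing")
})

test_that("ring transitions ramp linearly over a 0.05 mm half-width", {
  rings <- design_spec("concentric_rings", add_D = 1.5,
                       params = list(zone_radii_mm = 1.0,
                                     zone_powers_D = c(1.5, 0)))
  v <- evaluate_design(rings, c(0.94, 0.95, 1.0, 1.05, 1.06))$rel_powers_D
  expect_equal(v[1], 1.5)
  expect_equal(v[2], 1.5)
  expect_equal(v[3], 0.75)    # ramp midpoint
  expect_equal(v[4], 0)
  expect_equal(v[5], 0)
})

test_that("simulated measurements are deterministic given a seed and carry the noise model", {
  spec <- fixture_designs()$aspheric_mid
  a <- simulate_measurement(spec, n_reps = 3, seed = 42)
  b <- simulate_measurement(spec, n_reps = 3, seed = 42)
  expect_identical(a, b)

  clean <- simulate_measurement(spec, n_reps = 3, noise_sd_D = 0)
  expect_equal(clean[[1]]$powers_D, clean[[3]]$powers_D)
  expect_equal(clean[[1]]$powers_D,
               evaluate_design(spec)$rel_powers_D + spec$distance_power_D)

  # Monte-Carlo check of the noise SD on a coarse radial grid
  many <- simulate_measurement(spec, radii_mm = seq(0, 3, by = 0.5),
                               n_reps = 200, noise_sd_D = 0.08, seed = 1)
  m <- vapply(many, `[[`, numeric(7), "powers_D")
  sds <- apply(m, 1, sd)
  expect_true(all(sds > 0.07 & sds < 0.09))

  expect_error(simulate_measurement(spec, noise_sd_D = -0.1), "nonnegative")
})

test_that("design averaging of simulated repetitions converges to the true design", {
  spec <- fixture_designs()$aspheric_high
  r <- seq(0, 3, by = 0.05)
  reps <- simulate_measurement(spec, radii_mm = r, n_reps = 100,
                               noise_sd_D = 0.08, seed = 3)
  avg <- relative_profile(average_repetitions(reps))
  truth <- evaluate_design(spec, r)$rel_powers_D
  expect_lt(sqrt(mean((avg$powers_D - truth)^2)), 0.02)
})

test_that("the spherical-aberration term shifts relative profiles with distance power", {
  mk <- function(dp) design_spec("aspheric_center_near", add_D = 1.5,
                                 params = list(half_radius_mm = 1.5),
                                 distance_power_D = dp, sa_slope_D_per_D = 0.2)
  neg <- evaluate_design(mk(-4), seq(0, 3, 0.5))$rel_powers_D
  pos <- evaluate_design(mk(4), seq(0, 3, 0.5))$rel_powers_D
  diffs <- pos - neg
  expect_equal(diffs[1], 0)
  expect_equal(max(abs(diffs)), 8 * 0.2, tolerance = 1e-12)  # at r = 3 mm
  expect_true(all(diff(abs(diffs)) >= 0))                    # quadratic growth
})
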