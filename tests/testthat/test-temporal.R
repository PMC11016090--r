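test_that("temporal program invariants are enforced", {
  p <- temporal_program(seq(0, 1, 0.1), rep(1 / 11, 11))
  expect_equal(sum(p$coefficients), 1)
  expect_error(temporal_program(c(0, 0.15), c(0.5, 0.5)), "0.1 D")
  expect_error(temporal_program(c(0, 0.1), c(0.6, 0.6)), "sum to 1")
  expect_error(temporal_program(c(0, 0.1), c(1.4, -0.4)), "nonnegative")
  n <- temporal_program(c(0, 0.1), c(3, 1), normalize = TRUE)
  expect_equal(n$coefficients, c(0.75, 0.25))
})

test_that("a single-coefficient program reproduces the matching monofocal lens", {
  cfg <- fast_cfg(grid_n = 128L, focus_grid_D = seq(-1, 3, by = 0.05))
  prog <- temporal_program(1.0, 1.0)
  sim <- program_tf_vs(prog, 4.0, cfg)
  pk <- peak_focus(sim)
  expect_lt(abs(pk["focus_D"] - 1.0), 0.025)
  expect_gt(pk["value"], 0.99)
  # the radially binned program path agrees with the full 2-D computation
  direct <- tf_vs(constant_design(1.0), 4.0, cfg)
  expect_lt(max(abs(sim$values - direct$values)), 0.005)
})

test_that("the combined OTF is affine in the coefficients", {
  cfg <- fast_cfg(grid_n = 64L, focus_grid_D = seq(0, 1, by = 0.1))
  steps <- seq(0, 1, by = 0.1)
  table <- mclsim:::monofocal_otf_table(
    3.0, cfg, mclsim:::needed_defocus(cfg$focus_grid_D, steps))
  c1 <- rep(0, 11); c1[2] <- 1
  c2 <- rep(0, 11); c2[8] <- 1
  mix <- 0.3 * c1 + 0.7 * c2
  # mixture OTF equals mixture of OTFs exactly, per focus and radial bin
  for (F in c(0, 0.5)) {
    idx <- mclsim:::table_columns(table, abs(F - steps))
    S_mix <- table$B[, idx] %*% mix
    S_sep <- 0.3 * table$B[, idx] %*% c1 + 0.7 * table$B[, idx] %*% c2
    expect_equal(S_mix, S_sep, tolerance = 1e-15)
  }
})

test_that("an equal two-state program shows both focus peaks", {
  cfg <- fast_cfg(grid_n = 128L, focus_grid_D = seq(-1, 4, by = 0.05))
  prog <- temporal_program(seq(0, 3, 0.1), c(0.5, rep(0, 29), 0.5))
  sim <- program_tf_vs(prog, 4.0, cfg)
  expect_lt(abs(peak_focus(sim, c(-0.5, 0.5))["focus_D"]), 0.20)
  expect_lt(abs(peak_focus(sim, c(2.5, 3.5))["focus_D"] - 3.0), 0.20)
  # peak VS of a mixture cannot beat the best single state
  single <- program_tf_vs(temporal_program(0, 1), 4.0, cfg)
  expect_lte(max(sim$values), max(single$values) + 1e-9)
})

test_that("fitting a monofocal target concentrates the program mass at its focus", {
  cfg <- fast_cfg(grid_n = 128L, focus_grid_D = seq(-2, 4, by = 0.05))
  target <- tf_vs(constant_design(1.0), 4.0, cfg)
  prog <- fit_temporal_coefficients(target, 4.0, cfg, seed = 1)
  near <- abs(prog$focus_steps_D - 1.0) <= 0.1 + 1e-9
  expect_gte(sum(prog$coefficients[near]), 0.95)
})

test_that("refitting a program's own curve reproduces it (curve-space identifiability)", {
  cfg <- fast_cfg(grid_n = 128L, focus_grid_D = seq(-2, 4, by = 0.05))
  truth <- temporal_program(seq(0, 2, 0.1), c(0.5, rep(0, 9), 0.3, rep(0, 9), 0.2))
  target <- program_tf_vs(truth, 4.0, cfg)
  prog <- fit_temporal_coefficients(target, 4.0, cfg, seed = 2)
  refit <- program_tf_vs(prog, 4.0, cfg)
  expect_lt(curve_rmse(target, refit, c(-1, 4)), 0.01)
})

test_that("fit rejects invalid targets", {
  va <- tf_curve(seq(-2, 4, 0.5), rep(0.1, 13), metric_kind = "VA")
  expect_error(fit_temporal_coefficients(va, 4.0, fast_cfg()), "VS")
  narrow <- tf_curve(seq(0, 1, 0.05), rep(0.5, 21), metric_kind = "VS")
  expect_error(fit_temporal_coefficients(narrow, 4.0, fast_cfg()), "fit range")
})

test_that("bench validation applies the 0.20 D / 0.05 RMSE criteria", {
  f <- seq(-2, 4.5, by = 0.05)
  target <- tf_curve(f, 0.1 + 0.8 * exp(-(f - 1)^2 / 0.5), metric_kind = "VS")

  same <- validate_bench(target, target)
  expect_equal(same$rmse, 0)
  expect_equal(same$peak_shift_D, 0)
  expect_true(same$passed)

  shifted <- tf_curve(f, 0.1 + 0.8 * exp(-(f - 1.3)^2 / 0.5), metric_kind = "VS")
  rep_shift <- validate_bench(target, shifted)
  expect_equal(rep_shift$peak_shift_D, 0.30, tolerance = 1e-6)
  expect_false(rep_shift$passed)

  offset <- tf_curve(f, pmin(target$values + 0.06, 1), metric_kind = "VS")
  rep_off <- validate_bench(target, offset)
  expect_equal(rep_off$rmse, 0.06, tolerance = 1e-9)
  expect_false(rep_off$passed)

  short <- tf_curve(seq(-1, 2, 0.05), rep(0.5, 61), metric_kind = "VS")
  expect_error(validate_bench(target, short), "validation")
})

test_that("power traces visit each state proportionally and are recoverable", {
  prog <- temporal_program(seq(0, 0.5, 0.1), c(0.4, 0.1, 0, 0.2, 0, 0.3))
  tr <- simulate_power_trace(prog, n_periods = 50)
  rec <- recover_program(tr, prog$focus_steps_D)
  quant <- 1 / (nrow(tr) / 50)   # per-period sample quantization
  expect_lt(max(abs(rec$coefficients - prog$coefficients)), quant + 1e-9)

  const <- simulate_power_trace(temporal_program(1.5, 1), n_periods = 3)
  expect_true(all(const$power_D == 1.5))

  jittered <- simulate_power_trace(prog, n_periods = 100, jitter_sd_D = 0.02,
                                   seed = 8)
  recj <- recover_program(jittered, prog$focus_steps_D)
  expect_lt(max(abs(recj$coefficients - prog$coefficients)), 0.02)
})
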