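#' Temporal-multiplexing program
#'
#' Time coefficients of a temporal-multiplexing visual simulation: the
#' fraction of each cycle an optotunable lens dwells at each focus state,
#' on a uniform grid of 0.1 D steps. Cycling faster than flicker fusion
#' makes the eye perceive the time-averaged PSF, so a program acts as a
#' programmable multifocal element.
#'
#' @param focus_steps_D Focus states in diopters; uniform 0.1 D spacing.
#' @param coefficients Nonnegative time fractions, one per step, summing to
#'   1 (within 1e-9 unless `normalize = TRUE`).
#' @param normalize If `TRUE`, rescale the coefficients to unit sum instead
#'   of rejecting them.
#' @return An object of class `temporal_program`.
#' @export
temporal_program <- function(focus_steps_D, coefficients, normalize = FALSE) {
  assert_numeric(focus_steps_D, "focus_steps_D")
  assert_numeric(coefficients, "coefficients")
  if (length(focus_steps_D) != length(coefficients))
    validation_error("focus_steps_D and coefficients must have equal length")
  if (length(focus_steps_D) > 1L &&
      max(abs(diff(focus_steps_D) - 0.1)) > 1e-8)
    validation_error("focus steps must be spaced exactly 0.1 D apart")
  if (any(coefficients < -1e-12))
    validation_error("coefficients must be nonnegative")
  coefficients <- pmax(coefficients, 0)
  s <- sum(coefficients)
  if (normalize) {
    if (s <= 0) validation_error("cannot normalize an all-zero program")
    coefficients <- coefficients / s
  } else if (abs(s - 1) > 1e-9) {
    validation_error("coefficients must sum to 1 (got %.12f)", s)
  }
  structure(list(focus_steps_D = as.numeric(focus_steps_D),
                 coefficients = as.numeric(coefficients)),
            class = "temporal_program")
}

#' @export
print.temporal_program <- function(x, ...) {
  on <- x$coefficients > 0
  cat(sprintf("<temporal_program> %d steps on [%.1f, %.1f] D, %d active\n",
              length(x$focus_steps_D), min(x$focus_steps_D),
              max(x$focus_steps_D), sum(on)))
  fit <- attr(x, "fit")
  if (!is.null(fit$rmse))
    cat(sprintf("  fitted: RMSE %.4f over [%.2f, %.2f] D\n",
                fit$rmse, fit$fit_range_D[1L], fit$fit_range_D[2L]))
  invisible(x)
}

# --- monofocal OTF table ----------------------------------------------------
#
# The OTF of a program state differs from the target focus F only through
# pure defocus F - a_k, and defocus OTFs are even in the defocus sign. All
# quantities entering Visual Strehl are radial, so the CSF-masked OTF pixels
# are collapsed into unit-pixel radial bins: B[b, j] is the CSF-weighted
# mean OTF in bin b at |defocus| j, w_b the total CSF weight of the bin.
# This loses nothing material (the OTF is a smooth radial function sampled
# at sub-pixel radius scatter) and makes program evaluation essentially free.

monofocal_otf_table <- function(pupil_diameter_mm, cfg, defocus_abs_D) {
  key <- sort(unique(round(abs(defocus_abs_D), 9)))
  n <- cfg$grid_n
  N <- as.integer(n * cfg$pad_factor)
  pixel_mm <- pupil_diameter_mm / n
  lambda_m <- cfg$wavelength_nm * 1e-9
  ax_m <- centered_axis_mm(n, pixel_mm) * 1e-3
  rr2 <- outer(ax_m^2, ax_m^2, `+`)
  inside <- sqrt(rr2) < (pupil_diameter_mm / 2) * 1e-3
  defocus_scale <- (2 * pi / lambda_m) * rr2[inside] / 2
  J <- fft_embed_index(n, N)

  pitch <- freq_pitch_cpd(pixel_mm, cfg$wavelength_nm)
  k <- fft_offsets(N)
  kr <- sqrt(outer(k^2, k^2, `+`))
  wts <- csf_weights(pitch * kr, cfg$csf_params, cfg$max_freq_cpd)
  sel <- which(wts > 0)
  wsel <- wts[sel]
  rbin <- as.integer(round(kr[sel]))
  grp <- factor(rbin)
  w_b <- as.numeric(rowsum(wsel, grp))

  cols <- vapply(key, function(d) {
    block <- matrix(0 + 0i, n, n)
    block[inside] <- exp(-1i * d * defocus_scale)
    field <- matrix(0 + 0i, N, N)
    field[J, J] <- block
    otf <- Re(otf_from_field(field))
    as.numeric(rowsum(wsel * otf[sel], grp)) / w_b
  }, numeric(nlevels(grp)))
  B <- matrix(cols, nrow = nlevels(grp))

  i0 <- match(0, key)
  dl <- if (!is.na(i0)) B[, i0] else {
    # table without the in-focus column: compute the reference separately
    block <- matrix(0 + 0i, n, n); block[inside] <- 1 + 0i
    field <- matrix(0 + 0i, N, N); field[J, J] <- block
    otf <- Re(otf_from_field(field))
    as.numeric(rowsum(wsel * otf[sel], grp)) / w_b
  }
  list(defocus_abs = key, B = B, w_b = w_b, norm = sum(w_b * abs(dl)),
       pupil_diameter_mm = pupil_diameter_mm)
}

table_columns <- function(table, dabs) {
  idx <- match(round(dabs, 9), table$defocus_abs)
  if (anyNA(idx))
    validation_error("internal OTF table does not cover defocus %.2f D",
                     dabs[which(is.na(idx))[1L]])
  idx
}

needed_defocus <- function(focus_D, steps_D) {
  unique(round(abs(as.numeric(outer(focus_D, steps_D, `-`))), 9))
}

#' Through-focus Visual Strehl of a temporal program
#'
#' Simulates the optical performance of a temporal-multiplexing program:
#' the time-averaged PSF at evaluation focus F is the convex mixture of
#' monofocal PSFs displaced by the program steps,
#' `sum_k c_k PSF(F - a_k)`; equivalently the combined OTF is the same
#' mixture of monofocal OTFs (incoherent, intensity-level superposition).
#' Visual Strehl is computed from the modulus of the combined OTF against
#' the diffraction-limited reference of the same pupil.
#'
#' @param prog A [temporal_program()].
#' @param pupil_diameter_mm Pupil diameter in mm.
#' @param cfg An [optics_config()]; the curve is evaluated on
#'   `cfg$focus_grid_D`.
#' @param otf_table Optional precomputed monofocal OTF table (a program
#'   fitted by [fit_temporal_coefficients()] carries one as its
#'   `otf_table` attribute and it is reused automatically when it matches
#'   the requested pupil and grid).
#' @return A [tf_curve()] of metric kind `"VS"`.
#' @export
program_tf_vs <- function(prog, pupil_diameter_mm, cfg = optics_config(),
                          otf_table = NULL) {
  stopifnot(inherits(prog, "temporal_program"))
  need <- needed_defocus(cfg$focus_grid_D, prog$focus_steps_D)
  table <- otf_table %||% attr(prog, "otf_table")
  if (is.null(table) ||
      abs(table$pupil_diameter_mm - pupil_diameter_mm) > 1e-9 ||
      anyNA(match(round(need, 9), table$defocus_abs)))
    table <- monofocal_otf_table(pupil_diameter_mm, cfg, need)
  vals <- program_vs_values(prog$coefficients, prog$focus_steps_D,
                            cfg$focus_grid_D, table)
  tf_curve(cfg$focus_grid_D, pmin(pmax(vals, 0), 1),
           metric_kind = "VS", pupil_diameter_mm = pupil_diameter_mm)
}

# VS of a coefficient vector on a focus grid, given the OTF table
program_vs_values <- function(coef, steps_D, focus_D, table) {
  vapply(focus_D, function(F) {
    idx <- table_columns(table, abs(F - steps_D))
    S <- as.numeric(table$B[, idx, drop = FALSE] %*% coef)
    sum(table$w_b * abs(S)) / table$norm
  }, numeric(1L))
}

#' Fit temporal coefficients to a target through-focus curve
#'
#' Calculates the temporal-multiplexing program whose simulated TF-VS
#' matches a target TF-VS: nonnegative, unit-sum time coefficients on a
#' 0.1 D step grid minimizing the RMSE between [program_tf_vs()] and the
#' target over the fit range. Two-stage solver: (1) initialization by
#' nonnegative least squares on the OTF-linear superposition model (with the
#' unit-sum constraint imposed through an augmented row), (2) refinement by
#' projected-gradient minimization of the true VS-space RMSE on the
#' probability simplex, with a few deterministic random restarts.
#' Coefficients below `prune_tol` are pruned and the remainder renormalized
#' and re-polished on the pruned support.
#'
#' @param target A [tf_curve()] with `metric_kind = "VS"` covering
#'   `fit_range_D`.
#' @param pupil_diameter_mm Pupil diameter in mm.
#' @param cfg An [optics_config()].
#' @param fit_range_D Interval over which the RMSE is minimized (default
#'   -1.00 to +4.00 D, the dioptric range of interest of the bench
#'   validation).
#' @param step_span_D Span of the program's 0.1 D step grid (default -0.5
#'   to +4.0 D relative to distance focus).
#' @param seed Integer seed for the randomized restarts (fit is
#'   deterministic given the seed).
#' @param n_restarts Number of perturbed restarts (default 2).
#' @param max_iter Projected-gradient iteration cap per start (default 400).
#' @param prune_tol Coefficient pruning threshold (default 1e-3; dwell times
#'   below ~0.1% of a cycle are not realizable in hardware).
#' @return A [temporal_program()] with a `fit` attribute (achieved RMSE,
#'   fit range, pupil).
#' @export
fit_temporal_coefficients <- function(target, pupil_diameter_mm,
                                      cfg = optics_config(),
                                      fit_range_D = c(-1, 4),
                                      step_span_D = c(-0.5, 4),
                                      seed = 1L, n_restarts = 2L,
                                      max_iter = 400L, prune_tol = 1e-3) {
  stopifnot(inherits(target, "tf_curve"))
  if (!identical(target$metric_kind, "VS"))
    validation_error("fit target must be a VS curve, got %s", target$metric_kind)
  if (min(target$focus_D) > fit_range_D[1L] + 1e-9 ||
      max(target$focus_D) < fit_range_D[2L] - 1e-9)
    validation_error("target curve does not cover the fit range [%.2f, %.2f] D",
                     fit_range_D[1L], fit_range_D[2L])
  F_fit <- cfg$focus_grid_D[cfg$focus_grid_D >= fit_range_D[1L] - 1e-9 &
                            cfg$focus_grid_D <= fit_range_D[2L] + 1e-9]
  if (length(F_fit) < 4L)
    validation_error("fewer than 4 focus-grid points inside the fit range")
  y <- stats::approx(target$focus_D, target$values, xout = F_fit,
                     ties = "ordered")$y
  a <- seq(step_span_D[1L], step_span_D[2L], by = 0.1)
  K <- length(a)
  table <- monofocal_otf_table(
    pupil_diameter_mm, cfg,
    needed_defocus(c(cfg$focus_grid_D, F_fit), a))
  IDX <- vapply(seq_len(K),
                function(k) table_columns(table, abs(F_fit - a[k])),
                integer(length(F_fit)))

  wb <- table$w_b; Bm <- table$B; nrm <- table$norm
  nF <- length(F_fit)

  vs_of <- function(coef, support = seq_len(K)) {
    vapply(seq_len(nF), function(i) {
      S <- Bm[, IDX[i, support], drop = FALSE] %*% coef[support]
      sum(wb * abs(S)) / nrm
    }, numeric(1L))
  }
  obj <- function(coef, support = seq_len(K)) {
    r <- vs_of(coef, support) - y
    mean(r * r)
  }
  grad <- function(coef, support = seq_len(K)) {
    g <- numeric(length(support))
    vs <- numeric(nF)
    sgn_list <- vector("list", nF)
    for (i in seq_len(nF)) {
      S <- as.numeric(Bm[, IDX[i, support], drop = FALSE] %*% coef[support])
      vs[i] <- sum(wb * abs(S)) / nrm
      sgn_list[[i]] <- wb * sign(S) / nrm
    }
    r <- vs - y
    for (i in seq_len(nF)) {
      g <- g + (2 * r[i] / nF) *
        as.numeric(crossprod(Bm[, IDX[i, support], drop = FALSE], sgn_list[[i]]))
    }
    g
  }

  pgd <- function(coef, support = seq_len(K), iters = max_iter) {
    f <- obj(coef, support)
    eta <- 0.1
    for (it in seq_len(iters)) {
      g <- grad(coef, support)
      improved <- FALSE
      for (bt in 1:30) {
        cand <- project_simplex(coef[support] - eta * g)
        full <- coef; full[support] <- cand
        fc <- obj(full, support)
        if (fc < f - 1e-15) {
          coef <- full; f <- fc; eta <- eta * 1.5; improved <- TRUE
          break
        }
        eta <- eta / 2
      }
      if (!improved || eta < 1e-12) break
    }
    list(coef = coef, obj = f)
  }

  # stage 1: NNLS on the signed OTF-linear model, unit sum via augmented row
  A <- matrix(0, nF, K)
  for (k in seq_len(K)) A[, k] <- colSums(wb * Bm[, IDX[, k], drop = FALSE]) / nrm
  mu <- 10
  sol <- tryCatch(
    pracma::lsqnonneg(rbind(A, rep(mu, K)), c(y, mu))$x,
    error = function(e) rep(1 / K, K))
  if (sum(sol) <= 0) sol <- rep(1 / K, K)
  init <- sol / sum(sol)

  # stage 2: projected-gradient refinement with deterministic restarts
  set.seed(seed)
  starts <- list(init)
  if (n_restarts > 0) {
    for (j in seq_len(n_restarts)) {
      dirich <- stats::rgamma(K, shape = 1)
      starts[[j + 1L]] <- 0.7 * init + 0.3 * dirich / sum(dirich)
    }
  }
  fits <- lapply(starts, pgd)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "obj"))]]
  coef <- best$coef

  # prune unrealizably small dwell fractions, renormalize, re-polish
  coef[coef < prune_tol] <- 0
  if (sum(coef) <= 0) validation_error("temporal fit collapsed to an empty program")
  coef <- coef / sum(coef)
  support <- which(coef > 0)
  coef <- pgd(coef, support, iters = max_iter %/% 2)$coef

  prog <- temporal_program(a, coef)
  attr(prog, "fit") <- list(
    rmse = sqrt(obj(coef)), fit_range_D = fit_range_D,
    pupil_diameter_mm = pupil_diameter_mm, seed = seed,
    n_active = sum(coef > 0))
  attr(prog, "otf_table") <- table
  prog
}

#' Bench-validation report for a simulated through-focus curve
#'
#' Applies the bench acceptance criteria of temporal-multiplexing
#' simulations: the simulation passes if the TF-VS peak location differs
#' from the target by less than 0.20 D and the RMSE between the curves over
#' the dioptric range of interest (default -1.00 to +4.00 D) is below 0.05.
#' Curves on different grids are interpolated onto the finer grid restricted
#' to the validation range; peak locations use three-point parabolic
#' refinement.
#'
#' @param target,simulated [tf_curve()] objects covering `range_D`.
#' @param range_D Validation interval in diopters.
#' @return An object of class `bench_report` with elements `peak_shift_D`,
#'   `rmse`, `validation_range_D` and `passed`.
#' @export
validate_bench <- function(target, simulated, range_D = c(-1, 4)) {
  stopifnot(inherits(target, "tf_curve"), inherits(simulated, "tf_curve"))
  for (tf in list(target, simulated)) {
    if (min(tf$focus_D) > range_D[1L] + 1e-9 ||
        max(tf$focus_D) < range_D[2L] - 1e-9)
      validation_error("curve covers [%.2f, %.2f] D but validation needs [%.2f, %.2f] D",
                       min(tf$focus_D), max(tf$focus_D), range_D[1L], range_D[2L])
  }
  step_t <- min(diff(target$focus_D))
  step_s <- min(diff(simulated$focus_D))
  fine <- if (step_t <= step_s) target$focus_D else simulated$focus_D
  grid <- fine[fine >= range_D[1L] - 1e-9 & fine <= range_D[2L] + 1e-9]
  yt <- stats::approx(target$focus_D, target$values, xout = grid, ties = "ordered")$y
  ys <- stats::approx(simulated$focus_D, simulated$values, xout = grid, ties = "ordered")$y
  rmse <- sqrt(mean((yt - ys)^2))
  shift <- abs(peak_focus(target, range_D)["focus_D"] -
               peak_focus(simulated, range_D)["focus_D"])
  structure(list(peak_shift_D = unname(shift), rmse = rmse,
                 validation_range_D = range_D,
                 passed = unname(shift) < 0.20 && rmse < 0.05),
            class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  cat(sprintf("<bench_report> peak shift %.3f D, RMSE %.4f over [%.2f, %.2f] D: %s\n",
              x$peak_shift_D, x$rmse, x$validation_range_D[1L],
              x$validation_range_D[2L], if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Simulate the optical-power trace of a temporal program
#'
#' Emulates a high-speed focimeter recording of an optotunable lens driven
#' by a temporal program: a periodic schedule dwells at each focus step for
#' a time proportional to its coefficient and is sampled at the camera
#' rate, optionally with Gaussian power jitter.
#'
#' @param prog A [temporal_program()].
#' @param period_ms Cycle period in milliseconds (default 20, i.e. 50 Hz,
#'   beyond flicker fusion).
#' @param sample_rate_hz Sampling rate in Hz (default 3823, the high-speed
#'   camera frame rate).
#' @param n_periods Number of cycles to record.
#' @param jitter_sd_D Gaussian power jitter SD in diopters (default 0).
#' @param seed Optional seed for the jitter.
#' @return A data frame with columns `time_s` and `power_D`.
#' @seealso [recover_program()]
#' @export
simulate_power_trace <- function(prog, period_ms = 20, sample_rate_hz = 3823,
                                 n_periods = 10L, jitter_sd_D = 0, seed = NULL) {
  stopifnot(inherits(prog, "temporal_program"))
  if (!is_scalar_number(period_ms) || period_ms <= 0 ||
      !is_scalar_number(sample_rate_hz) || sample_rate_hz <= 0)
    parameter_error("period and sample rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  period_s <- period_ms / 1000
  n_samp <- floor(n_periods * period_s * sample_rate_hz)
  t <- (seq_len(n_samp) - 1L) / sample_rate_hz
  phase <- (t %% period_s) / period_s
  cum <- cumsum(c(0, prog$coefficients))
  cum[length(cum)] <- 1 + 1e-12
  k <- findInterval(phase, cum, rightmost.closed = TRUE)
  pw <- prog$focus_steps_D[k]
  if (jitter_sd_D > 0) pw <- pw + stats::rnorm(n_samp, 0, jitter_sd_D)
  data.frame(time_s = t, power_D = pw)
}

#' Recover a temporal program from a power trace
#'
#' Histograms a recorded optical-power trace into 0.1 D bins; the occupancy
#' fraction of each bin estimates the program coefficient of that focus
#' step.
#'
#' @param trace Data frame with a `power_D` column (see
#'   [simulate_power_trace()]).
#' @param focus_steps_D Step grid of the recovered program; defaults to the
#'   0.1 D grid spanning the rounded trace powers.
#' @return A [temporal_program()].
#' @export
recover_program <- function(trace, focus_steps_D = NULL) {
  p <- trace$power_D
  snapped <- round(p / 0.1) * 0.1
  if (is.null(focus_steps_D))
    focus_steps_D <- seq(min(snapped), max(snapped) + 1e-9, by = 0.1)
  idx <- round((snapped - focus_steps_D[1L]) / 0.1) + 1L
  keep <- idx >= 1L & idx <= length(focus_steps_D)
  counts <- tabulate(idx[keep], nbins = length(focus_steps_D))
  temporal_program(focus_steps_D, counts / sum(counts))
}
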