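#' Depth of focus of a through-focus Visual Strehl curve
#'
#' The depth of focus (DoF) is the extent of the focus axis over which the
#' Visual Strehl ratio exceeds a threshold (0.12 by default, a conventional
#' acuity-loss criterion). Threshold crossings are located by linear
#' interpolation between grid points. Because multifocal curves can be
#' bimodal, both the total superthreshold measure (the primary value) and
#' the largest contiguous interval are reported.
#'
#' @param tf A [tf_curve()] with `metric_kind = "VS"`.
#' @param threshold VS threshold (default 0.12).
#' @return A list of class `dof` with `total_D`, `largest_D` and a
#'   two-column matrix `intervals` of superthreshold segments (diopters).
#'   A curve entirely below threshold gives zero DoF.
#' @export
depth_of_focus <- function(tf, threshold = 0.12) {
  stopifnot(inherits(tf, "tf_curve"))
  if (!identical(tf$metric_kind, "VS"))
    validation_error("depth of focus is defined on VS curves, got %s", tf$metric_kind)
  f <- tf$focus_D
  d <- tf$values - threshold
  n <- length(f)
  segs <- NULL
  open <- if (d[1L] > 0) f[1L] else NA_real_
  for (i in seq_len(n - 1L)) {
    if (d[i] <= 0 && d[i + 1L] > 0) {          # upward crossing
      open <- f[i] + (f[i + 1L] - f[i]) * (-d[i]) / (d[i + 1L] - d[i])
    } else if (d[i] > 0 && d[i + 1L] <= 0) {   # downward crossing
      close <- f[i] + (f[i + 1L] - f[i]) * d[i] / (d[i] - d[i + 1L])
      segs <- rbind(segs, c(open, close))
      open <- NA_real_
    }
  }
  if (!is.na(open)) segs <- rbind(segs, c(open, f[n]))
  if (is.null(segs)) {
    return(structure(list(total_D = 0, largest_D = 0,
                          intervals = matrix(numeric(0), 0, 2)),
                     class = "dof"))
  }
  widths <- segs[, 2L] - segs[, 1L]
  structure(list(total_D = sum(widths), largest_D = max(widths),
                 intervals = unname(segs)),
            class = "dof")
}

#' @export
print.dof <- function(x, ...) {
  cat(sprintf("<dof> total %.2f D (largest contiguous %.2f D, %d segment%s)\n",
              x$total_D, x$largest_D, nrow(x$intervals),
              if (nrow(x$intervals) == 1L) "" else "s"))
  invisible(x)
}

#' First-order partial correlation
#'
#' Pearson correlation between `x` and `y` after linearly removing the
#' influence of a covariate `z`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' Used to compare through-focus curves while controlling for the defocus
#' value itself.
#'
#' @param x,y,z Equal-length numeric vectors, length >= 4.
#' @return The partial correlation coefficient in \[-1, 1\].
#' @export
partial_correlation <- function(x, y, z) {
  assert_numeric(x, "x"); assert_numeric(y, "y"); assert_numeric(z, "z")
  n <- length(x)
  if (length(y) != n || length(z) != n)
    validation_error("x, y and z must have equal length")
  if (n < 4L)
    validation_error("partial correlation needs at least 4 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stopf("degenerate input: zero variance", class = "mclsim_undefined_result")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  if (den2 <= 1e-14)
    stopf("partial correlation undefined: a variable is collinear with the covariate",
          class = "mclsim_undefined_result")
  (rxy - rxz * ryz) / sqrt(den2)
}

#' Compare two through-focus curves
#'
#' Computes the study comparison statistics between a simulated curve `x`
#' and a reference curve `y` on matched focus points: the partial
#' correlation controlling for defocus, the RMSE, and the mean difference
#' `y - x` (reference minus simulation).
#'
#' @param x,y [tf_curve()] objects (same metric kind).
#' @param range_D Optional interval restricting the comparison.
#' @return A list of class `comparison_result` with `partial_r`, `rmse`,
#'   `n` and `mean_diff`.
#' @export
compare_curves <- function(x, y, range_D = NULL) {
  stopifnot(inherits(x, "tf_curve"), inherits(y, "tf_curve"))
  g <- common_grid(x, y, range_D)
  vx <- stats::approx(x$focus_D, x$values, xout = g, ties = "ordered")$y
  vy <- stats::approx(y$focus_D, y$values, xout = g, ties = "ordered")$y
  structure(list(partial_r = partial_correlation(vx, vy, g),
                 rmse = sqrt(mean((vx - vy)^2)),
                 n = length(g), mean_diff = mean(vy - vx)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> r_xy.z %.3f, RMSE %.4f, mean diff %+.4f (n = %d)\n",
              x$partial_r, x$rmse, x$mean_diff, x$n))
  invisible(x)
}

common_grid <- function(x, y, range_D = NULL) {
  lo <- max(min(x$focus_D), min(y$focus_D))
  hi <- min(max(x$focus_D), max(y$focus_D))
  if (!is.null(range_D)) {
    lo <- max(lo, range_D[1L]); hi <- min(hi, range_D[2L])
  }
  if (hi <= lo) validation_error("curves have no overlapping focus range")
  fine <- if (min(diff(x$focus_D)) <= min(diff(y$focus_D))) x$focus_D else y$focus_D
  g <- fine[fine >= lo - 1e-9 & fine <= hi + 1e-9]
  if (length(g) < 2L) validation_error("fewer than 2 overlapping focus points")
  g
}

#' RMSE between two through-focus curves
#'
#' Root-mean-square difference over matched focus points inside a range,
#' in the units of the curves (VS ratio or logMAR). Curves on different
#' grids are interpolated onto the finer grid restricted to the overlap.
#'
#' @param x,y [tf_curve()] objects.
#' @param range_D Optional interval `c(lo, hi)`.
#' @return RMSE (nonnegative scalar).
#' @export
curve_rmse <- function(x, y, range_D = NULL) {
  g <- common_grid(x, y, range_D)
  vx <- stats::approx(x$focus_D, x$values, xout = g, ties = "ordered")$y
  vy <- stats::approx(y$focus_D, y$values, xout = g, ties = "ordered")$y
  sqrt(mean((vx - vy)^2))
}

#' Snap a measured pupil diameter to the simulation grid
#'
#' Simulated pupil sizes are precomputed on a 0.5 mm grid; a measured pupil
#' diameter is matched to the nearest 0.5 mm step, with exact midpoints
#' (x.25 / x.75 mm) rounding up.
#'
#' @param measured_mm Measured pupil diameter(s) in mm, in (0, 8].
#' @return Matched diameter(s) on the 0.5 mm grid.
#' @export
match_pupil_step <- function(measured_mm) {
  assert_numeric(measured_mm, "measured_mm")
  if (any(measured_mm <= 0 | measured_mm > 8))
    validation_error("pupil diameter must lie in (0, 8] mm")
  floor(measured_mm / 0.5 + 0.5) * 0.5
}
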