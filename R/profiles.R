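#' Radial power profile of a contact lens measurement
#'
#' A `power_profile` holds one radial power series of a (multifocal) contact
#' lens: local optical power P(r), in diopters, against semi-diameter r, in
#' mm, measured across a 6 mm optical zone (r from 0 to 3 mm). One object
#' corresponds to one repetition of one lens (family x addition label x
#' labeled distance power).
#'
#' @param radii_mm Strictly increasing, nonnegative semi-diameters in mm
#'   (maximum 3 mm).
#' @param powers_D Absolute local power (diopters) at each radius.
#' @param family Lens family label (character scalar).
#' @param add_label Addition label, conventionally one of `"Low"`, `"Mid"`,
#'   `"High"` (free-form labels are accepted).
#' @param distance_power_D Labeled distance power of the lens in diopters.
#' @param repetition Positive integer repetition index; `0` denotes a
#'   profile averaged over repetitions.
#' @param sd_D Optional pointwise standard deviation (diopters), attached by
#'   [average_repetitions()] as QC metadata.
#'
#' @return An object of class `power_profile`.
#' @seealso [smooth_profile()], [average_repetitions()], [relative_profile()],
#'   [average_design()]
#' @export
power_profile <- function(radii_mm, powers_D, family = "generic",
                          add_label = "Low", distance_power_D = 0,
                          repetition = 1L, sd_D = NULL) {
  assert_numeric(radii_mm, "radii_mm")
  assert_numeric(powers_D, "powers_D")
  if (length(radii_mm) != length(powers_D))
    validation_error("radii_mm and powers_D must have equal length")
  if (length(radii_mm) < 2L)
    validation_error("a power profile needs at least 2 samples")
  if (any(radii_mm < 0))
    validation_error("semi-diameters must be nonnegative")
  if (any(diff(radii_mm) <= 0))
    validation_error("radii_mm must be strictly increasing (duplicate or unordered radii)")
  if (max(radii_mm) > 3.0 + 1e-9)
    validation_error("maximum semi-diameter is 3.0 mm (6 mm optical zone), got %.3f", max(radii_mm))
  if (!is_scalar_number(distance_power_D))
    validation_error("distance_power_D must be a single finite number")
  if (!is.null(sd_D)) {
    assert_numeric(sd_D, "sd_D")
    if (length(sd_D) != length(radii_mm))
      validation_error("sd_D must match radii_mm in length")
  }
  structure(
    list(radii_mm = as.numeric(radii_mm), powers_D = as.numeric(powers_D),
         family = as.character(family), add_label = as.character(add_label),
         distance_power_D = as.numeric(distance_power_D),
         repetition = as.integer(repetition), sd_D = sd_D),
    class = "power_profile")
}

#' @export
print.power_profile <- function(x, ...) {
  cat(sprintf("<power_profile> %s / %s add / %+0.2f D distance, rep %d\n",
              x$family, x$add_label, x$distance_power_D, x$repetition))
  cat(sprintf("  %d samples, r in [%.2f, %.2f] mm, P in [%+0.2f, %+0.2f] D\n",
              length(x$radii_mm), min(x$radii_mm), max(x$radii_mm),
              min(x$powers_D), max(x$powers_D)))
  invisible(x)
}

#' Averaged relative power profile of a lens design
#'
#' A `design_profile` is the design-level relative power profile: the add
#' component only, obtained by subtracting the labeled distance power and
#' averaging across all measured distance powers of one design
#' (family x addition label).
#'
#' @param radii_mm Common radial grid in mm.
#' @param rel_powers_D Relative power (diopters) at each radius; the
#'   distance power has been subtracted, so a monofocal design is
#'   identically zero.
#' @param family,add_label Design labels.
#' @param n_distance_powers Number of distance powers averaged into the
#'   profile.
#'
#' @return An object of class `design_profile`.
#' @export
design_profile <- function(radii_mm, rel_powers_D, family = "generic",
                           add_label = "Low", n_distance_powers = 1L) {
  assert_numeric(radii_mm, "radii_mm")
  assert_numeric(rel_powers_D, "rel_powers_D")
  if (length(radii_mm) != length(rel_powers_D))
    validation_error("radii_mm and rel_powers_D must have equal length")
  if (any(diff(radii_mm) <= 0))
    validation_error("radii_mm must be strictly increasing")
  structure(
    list(radii_mm = as.numeric(radii_mm), rel_powers_D = as.numeric(rel_powers_D),
         family = as.character(family), add_label = as.character(add_label),
         n_distance_powers = as.integer(n_distance_powers)),
    class = "design_profile")
}

#' @export
print.design_profile <- function(x, ...) {
  cat(sprintf("<design_profile> %s / %s add (averaged over %d distance powers)\n",
              x$family, x$add_label, x$n_distance_powers))
  cat(sprintf("  %d samples, r in [%.2f, %.2f] mm, relative power in [%+0.2f, %+0.2f] D\n",
              length(x$radii_mm), min(x$radii_mm), max(x$radii_mm),
              min(x$rel_powers_D), max(x$rel_powers_D)))
  invisible(x)
}

#' Moving-average smoothing of a power profile
#'
#' Applies a centered moving average of odd window size over sample index,
#' the standard pre-processing step for deflectometry power profiles. At the
#' two ends of the series the window is truncated to the available samples,
#' so no data are invented beyond the measured domain. Radii are unchanged.
#'
#' @param p A [power_profile()].
#' @param window Odd positive integer window size (samples); default 5.
#' @return A smoothed `power_profile`.
#' @export
smooth_profile <- function(p, window = 5L) {
  stopifnot(inherits(p, "power_profile"))
  if (!is_scalar_number(window) || window < 1 || window %% 2 == 0)
    parameter_error("window must be an odd positive integer, got %s", format(window))
  n <- length(p$powers_D)
  if (window > n)
    parameter_error("window (%d) exceeds series length (%d)", window, n)
  h <- (window - 1L) / 2L
  cs <- cumsum(c(0, p$powers_D))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  p$powers_D <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  p
}

same_lens <- function(a, b) {
  identical(a$family, b$family) && identical(a$add_label, b$add_label) &&
    isTRUE(all.equal(a$distance_power_D, b$distance_power_D))
}

#' Average repeated measurements of one lens
#'
#' Pointwise arithmetic mean of repeated profile measurements of the same
#' lens. Profiles on a different radial grid than the first are linearly
#' interpolated onto the first grid. The pointwise standard deviation across
#' repetitions is attached as `sd_D` for repeatability QC; it is not
#' propagated into the downstream optics.
#'
#' @param reps A list of [power_profile()] objects with identical lens
#'   metadata (family, addition, distance power).
#' @return A `power_profile` with `repetition = 0` and `sd_D` set
#'   (`NA` when only one repetition is supplied).
#' @export
average_repetitions <- function(reps) {
  if (inherits(reps, "power_profile")) reps <- list(reps)
  if (!is.list(reps) || length(reps) == 0L)
    validation_error("need at least one profile to average")
  lapply(reps, function(p) stopifnot(inherits(p, "power_profile")))
  ref <- reps[[1L]]
  for (p in reps[-1L]) {
    if (!same_lens(ref, p))
      validation_error("cannot average repetitions with mixed lens metadata (%s/%s vs %s/%s)",
                       ref$family, ref$add_label, p$family, p$add_label)
  }
  mat <- vapply(reps, function(p) {
    if (length(p$radii_mm) == length(ref$radii_mm) &&
        max(abs(p$radii_mm - ref$radii_mm)) < 1e-9) p$powers_D
    else interp_profile(p$radii_mm, p$powers_D, ref$radii_mm)
  }, numeric(length(ref$radii_mm)))
  mat <- matrix(mat, nrow = length(ref$radii_mm))
  out <- ref
  out$powers_D <- rowMeans(mat)
  out$sd_D <- if (ncol(mat) > 1L) apply(mat, 1L, stats::sd) else rep(NA_real_, nrow(mat))
  out$repetition <- 0L
  out
}

#' Relative (add-only) power profile
#'
#' Subtracts the labeled distance power from an absolute power profile,
#' isolating the multifocal (addition) component. The operation is plain
#' pointwise subtraction and is therefore not idempotent: applying it twice
#' subtracts the distance power twice.
#'
#' @param p A [power_profile()] with `distance_power_D` set.
#' @return A `power_profile` whose powers are relative to distance power.
#' @export
relative_profile <- function(p) {
  stopifnot(inherits(p, "power_profile"))
  p$powers_D <- p$powers_D - p$distance_power_D
  p
}

#' Average relative profiles into a design-level profile
#'
#' Collapses relative profiles of one design measured at several distance
#' powers into a single [design_profile()]. Profiles are linearly
#' interpolated onto the union of their radial grids restricted to the
#' shared support, then averaged pointwise.
#'
#' @param rel_profiles List of relative [power_profile()] objects with the
#'   same `family` and `add_label`.
#' @return A [design_profile()] with `n_distance_powers` set to the number
#'   of profiles averaged.
#' @export
average_design <- function(rel_profiles) {
  if (inherits(rel_profiles, "power_profile")) rel_profiles <- list(rel_profiles)
  if (!is.list(rel_profiles) || length(rel_profiles) == 0L)
    validation_error("need at least one relative profile")
  lapply(rel_profiles, function(p) stopifnot(inherits(p, "power_profile")))
  ref <- rel_profiles[[1L]]
  for (p in rel_profiles[-1L]) {
    if (!identical(ref$family, p$family) || !identical(ref$add_label, p$add_label))
      validation_error("profiles from different designs: %s/%s vs %s/%s",
                       ref$family, ref$add_label, p$family, p$add_label)
  }
  lo <- max(vapply(rel_profiles, function(p) min(p$radii_mm), 0))
  hi <- min(vapply(rel_profiles, function(p) max(p$radii_mm), 0))
  if (hi <= lo)
    validation_error("radial supports do not overlap (shared support [%.3f, %.3f] mm)", lo, hi)
  grid <- sort(unique(unlist(lapply(rel_profiles, `[[`, "radii_mm"))))
  grid <- grid[grid >= lo - 1e-12 & grid <= hi + 1e-12]
  mat <- vapply(rel_profiles,
                function(p) interp_profile(p$radii_mm, p$powers_D, grid),
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  design_profile(grid, rowMeans(mat), family = ref$family,
                 add_label = ref$add_label,
                 n_distance_powers = length(rel_profiles))
}

#' Evaluate a design profile on arbitrary radii
#'
#' Linear interpolation of the relative power of a [design_profile()];
#' constant extrapolation is allowed for up to `slack` mm beyond the
#' measured support (the measured 3 mm semi-diameter meets the largest 6 mm
#' pupil zone only at its boundary).
#'
#' @param design A [design_profile()].
#' @param radii_mm Radii (mm) at which to evaluate.
#' @param slack Permitted constant extrapolation in mm (default 0.1).
#' @return Numeric vector of relative powers (D).
#' @export
design_power_at <- function(design, radii_mm, slack = 0.1) {
  stopifnot(inherits(design, "design_profile"))
  interp_profile(design$radii_mm, design$rel_powers_D, radii_mm, slack = slack)
}
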