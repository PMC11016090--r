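#' Synthetic multifocal lens design specification
#'
#' Defines a parametric lens-design archetype used to generate synthetic
#' relative power profiles with the structure seen in commercial daily
#' multifocal contact lenses: smooth aspheric center-near designs whose add
#' decays towards the periphery, and concentric-ring designs with a few
#' discrete power steps. A quadratic spherical-aberration-like term models
#' the dependence of the relative profile on the labeled distance power.
#'
#' @param archetype One of `"monofocal"`, `"aspheric_center_near"`,
#'   `"concentric_rings"`, `"pure_bifocal"`.
#' @param add_D Center addition in diopters (>= 0).
#' @param params Archetype-specific shape parameters:
#'   * aspheric_center_near: `half_radius_mm` — the radius at which the
#'     Gaussian add profile `add_D * exp(-(r/h)^2)` has fallen to 1/e.
#'   * concentric_rings / pure_bifocal: `zone_radii_mm` (strictly increasing
#'     boundary radii, <= 3 mm) and `zone_powers_D` (relative power of each
#'     zone; one more entry than boundaries). A pure bifocal has exactly one
#'     boundary (two zones).
#' @param distance_power_D Labeled distance power in diopters.
#' @param sa_slope_D_per_D Shift of the relative profile per diopter of
#'   distance power, applied as `sa_slope * distance_power * (r/3)^2`
#'   (spherical aberration contributes power quadratically in radius).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(archetype = c("monofocal", "aspheric_center_near",
                                      "concentric_rings", "pure_bifocal"),
                        add_D = 0, params = list(), distance_power_D = 0,
                        sa_slope_D_per_D = 0) {
  archetype <- match.arg(archetype)
  if (!is_scalar_number(add_D) || add_D < 0)
    validation_error("add_D must be a nonnegative number")
  if (archetype == "aspheric_center_near") {
    h <- params$half_radius_mm %||% 1.5
    if (!is_scalar_number(h) || h <= 0)
      validation_error("aspheric half_radius_mm must be positive")
    params$half_radius_mm <- h
  }
  if (archetype %in% c("concentric_rings", "pure_bifocal")) {
    b <- params$zone_radii_mm
    v <- params$zone_powers_D
    if (is.null(b) || is.null(v))
      validation_error("%s needs zone_radii_mm and zone_powers_D", archetype)
    if (any(diff(c(0, b)) <= 0) || max(b) > 3.0)
      validation_error("zone boundaries must be strictly increasing and <= 3.0 mm")
    if (length(v) != length(b) + 1L)
      validation_error("need one zone power more than zone boundaries")
    if (archetype == "pure_bifocal" && length(v) != 2L)
      validation_error("a pure bifocal has exactly 2 zones")
  }
  structure(list(archetype = archetype, add_D = add_D, params = params,
                 distance_power_D = distance_power_D,
                 sa_slope_D_per_D = sa_slope_D_per_D),
            class = "design_spec")
}

# piecewise-constant zones with a linear ramp of half-width `ramp` mm at
# each boundary; avoids wavefront-slope discontinuities that an instrument
# would low-pass anyway
zone_power <- function(r, boundaries, values, ramp = 0.05) {
  xs <- c(0)
  ys <- c(values[1L])
  for (j in seq_along(boundaries)) {
    xs <- c(xs, boundaries[j] - ramp, boundaries[j] + ramp)
    ys <- c(ys, values[j], values[j + 1L])
  }
  xs <- c(xs, max(3, max(r)) + 1)
  ys <- c(ys, values[length(values)])
  stats::approx(xs, ys, xout = r, rule = 2, ties = "ordered")$y
}

#' Evaluate a synthetic design's relative power profile
#'
#' @param spec A [design_spec()].
#' @param radii_mm Radii in mm within \[0, 3\].
#' @return A [design_profile()] on `radii_mm`.
#' @export
evaluate_design <- function(spec, radii_mm = seq(0, 3, by = 0.01)) {
  stopifnot(inherits(spec, "design_spec"))
  assert_numeric(radii_mm, "radii_mm")
  if (min(radii_mm) < 0 || max(radii_mm) > 3.0 + 1e-9)
    validation_error("radii must lie within [0, 3] mm")
  rel <- switch(spec$archetype,
    monofocal = rep(0, length(radii_mm)),
    aspheric_center_near =
      spec$add_D * exp(-(radii_mm / spec$params$half_radius_mm)^2),
    concentric_rings = ,
    pure_bifocal =
      zone_power(radii_mm, spec$params$zone_radii_mm, spec$params$zone_powers_D))
  rel <- rel + spec$sa_slope_D_per_D * spec$distance_power_D * (radii_mm / 3)^2
  design_profile(radii_mm, rel,
                 family = paste0("synthetic_", spec$archetype),
                 add_label = sprintf("%.2fD", spec$add_D),
                 n_distance_powers = 1L)
}

#' Simulate repeated power-profile measurements of a synthetic lens
#'
#' Generates absolute power profiles (distance power + relative design +
#' i.i.d. Gaussian measurement noise per sample and repetition), emulating
#' triplicate deflectometry measurements whose repeatability SD stays below
#' 0.10 D after smoothing.
#'
#' @param spec A [design_spec()].
#' @param radii_mm Measurement radii (default 0 to 3 mm in 0.01 mm steps).
#' @param n_reps Number of repetitions (default 3).
#' @param noise_sd_D Gaussian noise SD in diopters (default 0.08).
#' @param seed Optional integer seed; given a seed the output is
#'   deterministic.
#' @return A list of `n_reps` [power_profile()] objects.
#' @export
simulate_measurement <- function(spec, radii_mm = seq(0, 3, by = 0.01),
                                 n_reps = 3L, noise_sd_D = 0.08, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is_scalar_number(n_reps) || n_reps < 1)
    parameter_error("n_reps must be >= 1")
  if (!is_scalar_number(noise_sd_D) || noise_sd_D < 0)
    parameter_error("noise_sd_D must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  base <- evaluate_design(spec, radii_mm)$rel_powers_D + spec$distance_power_D
  lapply(seq_len(n_reps), function(k) {
    power_profile(radii_mm, base + stats::rnorm(length(base), 0, noise_sd_D),
                  family = paste0("synthetic_", spec$archetype),
                  add_label = sprintf("%.2fD", spec$add_D),
                  distance_power_D = spec$distance_power_D,
                  repetition = k)
  })
}

#' Frozen synthetic fixture designs
#'
#' A fixed set of synthetic design archetypes used throughout the test
#' suite and the bench-validation examples: three aspheric center-near
#' designs with increasing addition, a 50/50 (by area at a 4 mm pupil)
#' bifocal, and a concentric three-step ring design.
#'
#' @return Named list of [design_spec()] objects.
#' @export
fixture_designs <- function() {
  list(
    aspheric_low  = design_spec("aspheric_center_near", add_D = 0.5,
                                params = list(half_radius_mm = 1.5)),
    aspheric_mid  = design_spec("aspheric_center_near", add_D = 1.0,
                                params = list(half_radius_mm = 1.5)),
    aspheric_high = design_spec("aspheric_center_near", add_D = 1.5,
                                params = list(half_radius_mm = 1.5)),
    bifocal_5050  = design_spec("pure_bifocal", add_D = 3.0,
                                params = list(zone_radii_mm = sqrt(2),
                                              zone_powers_D = c(3.0, 0.0))),
    rings3        = design_spec("concentric_rings", add_D = 1.5,
                                params = list(zone_radii_mm = c(0.8, 1.5, 2.1),
                                              zone_powers_D = c(1.5, 0, 1.5, 0)))
  )
}
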