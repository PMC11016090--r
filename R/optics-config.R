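#' Fourier-optics configuration
#'
#' Collects the numerical and physiological parameters of the through-focus
#' Visual Strehl computation.
#'
#' @param wavelength_nm Light wavelength in nm (default 546, the e-line used
#'   by deflectometry power mapping).
#' @param grid_n Samples across the pupil diameter (default 512; powers of
#'   two keep the FFT fast).
#' @param pad_factor Zero-padding factor >= 2 for the PSF/OTF computation
#'   (default 2; exactly supports the incoherent cutoff frequency).
#' @param focus_grid_D Through-focus evaluation grid in diopters (default
#'   -2.00 to +4.00 D in 0.05 D steps); must be strictly increasing with a
#'   uniform step.
#' @param pupil_diameters_mm Pupil diameters evaluated by the pipeline
#'   (default 3 to 5 mm in 0.5 mm steps; must lie in (0, 6]).
#' @param max_freq_cpd Spatial-frequency cutoff of the contrast-sensitivity
#'   weighting, cycles/degree (default 60).
#' @param csf_params Constants `a`, `b`, `c` of the contrast-sensitivity
#'   weighting `CSF(f) = f^a * exp(-b * f^c)`; see [csf_weights()].
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(wavelength_nm = 546, grid_n = 512L, pad_factor = 2L,
                          focus_grid_D = seq(-2, 4, by = 0.05),
                          pupil_diameters_mm = seq(3, 5, by = 0.5),
                          max_freq_cpd = 60,
                          csf_params = list(a = 1, b = 0.09164, c = 1.1)) {
  if (!is_scalar_number(wavelength_nm) || wavelength_nm <= 0)
    parameter_error("wavelength_nm must be positive")
  if (!is_scalar_number(grid_n) || grid_n < 16)
    parameter_error("grid_n must be >= 16")
  if (!is_scalar_number(pad_factor) || pad_factor < 2)
    parameter_error("pad_factor must be >= 2")
  assert_numeric(focus_grid_D, "focus_grid_D")
  if (length(focus_grid_D) > 1L) {
    st <- diff(focus_grid_D)
    if (any(st <= 0) || max(abs(st - st[1L])) > 1e-9)
      parameter_error("focus_grid_D must be strictly increasing with uniform step")
  }
  assert_numeric(pupil_diameters_mm, "pupil_diameters_mm")
  if (any(pupil_diameters_mm <= 0 | pupil_diameters_mm > 6))
    parameter_error("pupil diameters must lie in (0, 6] mm")
  if (!is_scalar_number(max_freq_cpd) || max_freq_cpd <= 0)
    parameter_error("max_freq_cpd must be positive")
  stopifnot(all(c("a", "b", "c") %in% names(csf_params)))
  structure(list(wavelength_nm = wavelength_nm, grid_n = as.integer(grid_n),
                 pad_factor = as.integer(pad_factor),
                 focus_grid_D = as.numeric(focus_grid_D),
                 pupil_diameters_mm = as.numeric(pupil_diameters_mm),
                 max_freq_cpd = max_freq_cpd, csf_params = csf_params),
            class = "optics_config")
}

#' Neural contrast-sensitivity weighting
#'
#' Radial contrast-sensitivity function used to weight the MTF in the
#' Visual Strehl metric, in the generalized form
#' `CSF(f) = f^a * exp(-b * f^c)` with `f` in cycles/degree. The default
#' constants (`a = 1`, `b = 0.114^1.1 = 0.09164`, `c = 1.1`) follow the
#' classic Mannos-Sakrison band-pass model without its low-frequency
#' plateau, peaking near 8 cyc/deg; the overall scale is irrelevant because
#' Visual Strehl is a ratio. Frequencies beyond `max_freq_cpd` get weight
#' zero.
#'
#' @param freq_cpd Spatial frequencies in cycles/degree (vector or matrix).
#' @param params List with elements `a`, `b`, `c`.
#' @param max_freq_cpd Cutoff frequency (cycles/degree).
#' @return Nonnegative weights, same shape as `freq_cpd`.
#' @export
csf_weights <- function(freq_cpd, params = list(a = 1, b = 0.09164, c = 1.1),
                        max_freq_cpd = 60) {
  w <- freq_cpd^params$a * exp(-params$b * freq_cpd^params$c)
  w[freq_cpd > max_freq_cpd] <- 0
  w[!is.finite(w)] <- 0
  w
}

#' Through-focus curve
#'
#' A metric evaluated on a grid of defocus values: either the Visual Strehl
#' ratio (`"VS"`, dimensionless in \[0, 1\]) or clinical visual acuity
#' (`"VA"`, logMAR). Positive focus values correspond to near additions: a
#' center-near add of +A diopters produces a TF-VS feature at +A.
#'
#' @param focus_D Focus grid in diopters (strictly increasing).
#' @param values Metric values, same length as `focus_D`.
#' @param metric_kind `"VS"` or `"VA"`.
#' @param pupil_diameter_mm Pupil diameter the curve refers to (optional for
#'   VA curves).
#' @return An object of class `tf_curve`.
#' @export
tf_curve <- function(focus_D, values, metric_kind = c("VS", "VA"),
                     pupil_diameter_mm = NA_real_) {
  metric_kind <- match.arg(metric_kind)
  assert_numeric(focus_D, "focus_D")
  assert_numeric(values, "values")
  if (length(focus_D) != length(values))
    validation_error("focus_D and values must have equal length")
  if (any(diff(focus_D) <= 0))
    validation_error("focus_D must be strictly increasing")
  if (metric_kind == "VS" && (min(values) < -1e-9 || max(values) > 1 + 1e-6))
    validation_error("VS values must lie in [0, 1]")
  structure(list(focus_D = as.numeric(focus_D), values = as.numeric(values),
                 metric_kind = metric_kind,
                 pupil_diameter_mm = as.numeric(pupil_diameter_mm)),
            class = "tf_curve")
}

#' @export
print.tf_curve <- function(x, ...) {
  pk <- peak_focus(x)
  cat(sprintf("<tf_curve> %s, %s pupil, %d points on [%.2f, %.2f] D\n",
              x$metric_kind,
              if (is.na(x$pupil_diameter_mm)) "unspecified"
              else sprintf("%.1f mm", x$pupil_diameter_mm),
              length(x$focus_D), min(x$focus_D), max(x$focus_D)))
  cat(sprintf("  peak %.3f at %+0.2f D\n", pk["value"], pk["focus_D"]))
  invisible(x)
}

#' @export
plot.tf_curve <- function(x, ..., threshold = NULL) {
  graphics::plot(x$focus_D, x$values, type = "l",
                 xlab = "Defocus (D)",
                 ylab = if (x$metric_kind == "VS") "Visual Strehl" else "VA (logMAR)",
                 ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Refined peak location of a through-focus curve
#'
#' Locates the global maximum on the focus grid and refines it by a
#' three-point parabolic fit through the peak sample and its neighbors,
#' giving sub-grid-step resolution. Grid ties are broken towards the focus
#' value of smallest absolute value.
#'
#' @param tf A [tf_curve()].
#' @param range_D Optional interval `c(lo, hi)` restricting the search.
#' @return Named numeric vector with elements `focus_D` (refined peak
#'   location) and `value` (grid peak value).
#' @export
peak_focus <- function(tf, range_D = NULL) {
  stopifnot(inherits(tf, "tf_curve"))
  f <- tf$focus_D; v <- tf$values
  if (!is.null(range_D)) {
    keep <- f >= range_D[1L] - 1e-9 & f <= range_D[2L] + 1e-9
    if (sum(keep) < 2L)
      validation_error("fewer than 2 samples inside the peak-search range")
    f <- f[keep]; v <- v[keep]
  }
  vmax <- max(v)
  cand <- which(v >= vmax - 1e-12)
  i <- cand[which.min(abs(f[cand]))]
  loc <- f[i]
  if (i > 1L && i < length(f)) {
    den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    if (den < -1e-15) {
      step <- f[i + 1L] - f[i]
      off <- 0.5 * (v[i - 1L] - v[i + 1L]) / den
      loc <- f[i] + max(-0.5, min(0.5, off)) * step
    }
  }
  c(focus_D = loc, value = vmax)
}
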