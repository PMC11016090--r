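#' Wavefront map over a circular pupil
#'
#' Internal constructor for the 2-D optical path difference (OPD) map. The
#' map is sampled on an `n x n` grid whose pixel pitch is
#' `pupil_diameter_mm / n`, with the pupil center on an exact grid sample;
#' pixels outside the circular support are `NA`.
#'
#' @param opd_um `n x n` matrix of OPD in micrometers (`NA` outside the
#'   support).
#' @param pixel_mm Sample spacing in the pupil plane (mm).
#' @param pupil_diameter_mm Diameter of the circular support (mm).
#' @return An object of class `wavefront_map`.
#' @keywords internal
wavefront_map <- function(opd_um, pixel_mm, pupil_diameter_mm) {
  stopifnot(is.matrix(opd_um), nrow(opd_um) == ncol(opd_um))
  inside <- !is.na(opd_um)
  if (!all(is.finite(opd_um[inside])))
    validation_error("OPD must be finite inside the pupil support")
  structure(list(opd_um = opd_um, pixel_mm = pixel_mm,
                 pupil_diameter_mm = pupil_diameter_mm),
            class = "wavefront_map")
}

#' @export
print.wavefront_map <- function(x, ...) {
  rng <- range(x$opd_um, na.rm = TRUE)
  cat(sprintf("<wavefront_map> %.1f mm pupil, %d x %d grid (%.4f mm/px), OPD [%.3f, %.3f] um\n",
              x$pupil_diameter_mm, nrow(x$opd_um), ncol(x$opd_um),
              x$pixel_mm, rng[1L], rng[2L]))
  invisible(x)
}

# centered pixel coordinates (mm) for an n-point axis with the origin on a
# grid sample (index floor(n/2)+1)
centered_axis_mm <- function(n, pixel_mm) {
  (seq_len(n) - (floor(n / 2) + 1L)) * pixel_mm
}

#' Reconstruct the wavefront phase map from a relative power profile
#'
#' Builds the rotationally symmetric wavefront whose local (slope-based)
#' power reproduces the design's relative power profile:
#' `W(r) = integral of P(s) * s ds` from 0 to r, with P in diopters and s in
#' meters, so a constant power P gives the paraxial defocus wavefront
#' `W = P r^2 / 2`. The radial integral is evaluated by cumulative
#' trapezoidal quadrature on a fine radial grid and mapped to 2-D by radial
#' symmetry; `W(0) = 0`.
#'
#' Profiles falling short of the pupil semi-diameter by less than 0.1 mm are
#' constant-extrapolated; shorter support is an error.
#'
#' @param design A [design_profile()].
#' @param pupil_diameter_mm Pupil diameter in mm.
#' @param cfg An [optics_config()]; `grid_n` sets the map sampling.
#' @param n_fine Number of fine radial quadrature samples (default 4096).
#' @return A `wavefront_map` with OPD in micrometers.
#' @export
reconstruct_wavefront <- function(design, pupil_diameter_mm,
                                  cfg = optics_config(), n_fine = 4096L) {
  stopifnot(inherits(design, "design_profile"))
  semi <- pupil_diameter_mm / 2
  if (max(design$radii_mm) < semi - 0.1 - 1e-9)
    validation_error(
      "design support ends at %.3f mm but pupil semi-diameter is %.3f mm (> 0.1 mm short)",
      max(design$radii_mm), semi)
  r_mm <- seq(0, semi, length.out = n_fine)
  P <- design_power_at(design, r_mm, slack = 0.1 + semi * 1e-9)
  r_m <- r_mm * 1e-3
  W_m <- pracma::cumtrapz(r_m, P * r_m)[, 1L]
  W_um <- W_m * 1e6

  n <- cfg$grid_n
  pixel_mm <- pupil_diameter_mm / n
  ax <- centered_axis_mm(n, pixel_mm)
  rr <- sqrt(outer(ax^2, ax^2, `+`))
  opd <- matrix(NA_real_, n, n)
  inside <- rr < semi
  opd[inside] <- stats::approx(r_mm, W_um, xout = rr[inside], rule = 2)$y
  wavefront_map(opd, pixel_mm, pupil_diameter_mm)
}

#' Recover the local power profile from a wavefront map
#'
#' Inverse of [reconstruct_wavefront()]: extracts the radial OPD profile of
#' a rotationally symmetric map and converts it back to local power,
#' `P(r) = (1/r) dW/dr`, using centered finite differences; the on-axis
#' power `P(0)` comes from a parabolic fit `W = a r^2` to the innermost
#' samples. Maps that are not radially symmetric (beyond `tol_um`) are
#' rejected.
#'
#' @param w A `wavefront_map`.
#' @param tol_um Symmetry tolerance in micrometers (default 1e-3).
#' @return A [design_profile()] of the recovered local power on the pixel
#'   radius grid.
#' @export
local_power <- function(w, tol_um = 1e-3) {
  stopifnot(inherits(w, "wavefront_map"))
  n <- nrow(w$opd_um)
  c0 <- floor(n / 2) + 1L
  k_max <- n - c0        # radial samples available along +x
  along_x <- w$opd_um[c0, c0:(c0 + k_max)]
  along_y <- w$opd_um[c0:(c0 + k_max), c0]
  ok <- !is.na(along_x) & !is.na(along_y)
  if (max(abs(along_x[ok] - along_y[ok])) > tol_um)
    validation_error("wavefront map is not radially symmetric (max axis mismatch > %g um)", tol_um)
  keep <- which(ok)
  Wr <- along_x[keep]
  r_mm <- (keep - 1L) * w$pixel_mm
  r_m <- r_mm * 1e-3
  W_m <- Wr * 1e-6
  m <- length(r_m)
  if (m < 4L) validation_error("too few radial samples to differentiate")
  P <- rep(NA_real_, m)
  i <- 2:(m - 1L)
  dW <- (W_m[i + 1L] - W_m[i - 1L]) / (r_m[i + 1L] - r_m[i - 1L])
  P[i] <- dW / r_m[i]
  # parabolic fit through the innermost samples for the axial power
  j <- 2:min(4L, m)
  a <- sum(W_m[j] * r_m[j]^2) / sum(r_m[j]^4)
  P[1L] <- 2 * a
  P <- P[-m]
  design_profile(r_mm[-m], P, family = "recovered", add_label = "n/a")
}
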