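# Fourier-optics engine: generalized pupil function, PSF/OTF/MTF, Visual
# Strehl and the through-focus loop.
#
# Geometry. The pupil spans grid_n pixels; the complex field is embedded in
# an N = grid_n * pad_factor square held in FFT (wrap-around) order with the
# pupil center at element [1, 1]. With pad_factor 2 the OTF support (twice
# the pupil bandwidth) exactly fills the array. The OTF frequency pitch is
# pixel / wavelength cycles/radian, converted to cycles/degree by pi/180.

# FFT-order signed index offsets for an even-length axis
fft_offsets <- function(N) c(0:(N / 2 - 1L), -(N / 2):(-1L))

# map centered block indices (1..n with center floor(n/2)+1) to FFT-order
# indices in an N-length axis
fft_embed_index <- function(n, N) {
  m <- seq_len(n) - (floor(n / 2) + 1L)
  ifelse(m >= 0, m + 1L, N + m + 1L)
}

freq_pitch_cpd <- function(pixel_mm, wavelength_nm) {
  (pixel_mm * 1e-3) / (wavelength_nm * 1e-9) * (pi / 180)
}

#' Generalized pupil function
#'
#' Complex pupil field for a wavefront map evaluated at a given defocus:
#' amplitude 1 inside the circular support and 0 outside, phase
#' `(2*pi/lambda) * (W(r) - defocus * r^2 / 2)` with r in meters. A zone of
#' relative power F therefore has zero net phase curvature when evaluated at
#' focus F. The field is returned zero-padded in FFT order, ready for
#' [mtf()].
#'
#' @param w A `wavefront_map` (see [reconstruct_wavefront()]).
#' @param defocus_D Defocus (evaluation focus) in diopters.
#' @param cfg An [optics_config()] (wavelength and padding).
#' @return Complex `N x N` matrix of class `pupil_field` with sampling
#'   attributes.
#' @export
pupil_function <- function(w, defocus_D = 0, cfg = optics_config()) {
  stopifnot(inherits(w, "wavefront_map"))
  n <- nrow(w$opd_um)
  N <- as.integer(n * cfg$pad_factor)
  lambda_m <- cfg$wavelength_nm * 1e-9
  ax_m <- centered_axis_mm(n, w$pixel_mm) * 1e-3
  r2 <- outer(ax_m^2, ax_m^2, `+`)
  inside <- !is.na(w$opd_um)
  phase <- (2 * pi / lambda_m) *
    (w$opd_um[inside] * 1e-6 - defocus_D * r2[inside] / 2)
  block <- matrix(0 + 0i, n, n)
  block[inside] <- exp(1i * phase)
  field <- matrix(0 + 0i, N, N)
  J <- fft_embed_index(n, N)
  field[J, J] <- block
  structure(field, class = c("pupil_field", class(field)),
            pixel_mm = w$pixel_mm, wavelength_nm = cfg$wavelength_nm,
            pupil_diameter_mm = w$pupil_diameter_mm,
            n_support = sum(inside))
}

# raw complex OTF (FFT order, normalized to 1 at zero frequency)
otf_from_field <- function(field) {
  psf <- Mod(stats::fft(field))^2
  otf <- stats::fft(psf)
  otf / Re(otf[1L, 1L])
}

#' Modulation transfer function of a pupil field
#'
#' Computes `PSF = |FFT(pupil)|^2`, the OTF as the normalized Fourier
#' transform of the PSF (equivalent to the pupil autocorrelation), and the
#' MTF as its modulus, with `MTF(0) = 1`. The frequency axes are returned in
#' cycles/degree.
#'
#' @param field A `pupil_field` from [pupil_function()].
#' @param cfg An [optics_config()] (unused beyond validation; sampling is
#'   carried by the field's attributes).
#' @return Object of class `mtf_map`: list with `mtf` (matrix, FFT order),
#'   `otf` (complex matrix), `freq_cpd` (matrix of radial frequencies) and
#'   `pitch_cpd`.
#' @export
mtf <- function(field, cfg = optics_config()) {
  stopifnot(inherits(field, "pupil_field"))
  otf <- otf_from_field(field)
  N <- nrow(otf)
  pitch <- freq_pitch_cpd(attr(field, "pixel_mm"), attr(field, "wavelength_nm"))
  k <- fft_offsets(N)
  freq <- pitch * sqrt(outer(k^2, k^2, `+`))
  structure(list(mtf = Mod(otf), otf = otf, freq_cpd = freq, pitch_cpd = pitch,
                 pupil_diameter_mm = attr(field, "pupil_diameter_mm"),
                 wavelength_nm = attr(field, "wavelength_nm")),
            class = "mtf_map")
}

#' Visual Strehl ratio from MTFs
#'
#' The Visual Strehl ratio (MTF variant): the contrast-sensitivity-weighted
#' volume under the aberrated MTF divided by the same volume under the
#' diffraction-limited MTF of the same pupil, using frequencies up to
#' `cfg$max_freq_cpd`.
#'
#' @param mtf_aberrated,mtf_dl `mtf_map` objects on the same frequency grid.
#' @param cfg An [optics_config()] supplying the CSF constants and cutoff.
#' @return A single Visual Strehl value (dimensionless, in \[0, 1\] up to
#'   numerical noise).
#' @export
visual_strehl <- function(mtf_aberrated, mtf_dl, cfg = optics_config()) {
  stopifnot(inherits(mtf_aberrated, "mtf_map"), inherits(mtf_dl, "mtf_map"))
  if (!identical(dim(mtf_aberrated$mtf), dim(mtf_dl$mtf)) ||
      abs(mtf_aberrated$pitch_cpd - mtf_dl$pitch_cpd) > 1e-12 * mtf_dl$pitch_cpd)
    validation_error("MTF frequency grids do not match")
  w <- csf_weights(mtf_dl$freq_cpd, cfg$csf_params, cfg$max_freq_cpd)
  sum(w * mtf_aberrated$mtf) / sum(w * mtf_dl$mtf)
}

#' Through-focus Visual Strehl of a lens design
#'
#' The central optical computation: reconstructs the wavefront of a relative
#' power profile at the requested pupil diameter, then evaluates the Visual
#' Strehl ratio at every focus value of the configured grid by adding the
#' corresponding paraxial defocus to the pupil phase. The reference is the
#' diffraction-limited MTF of the same pupil.
#'
#' @param design A [design_profile()] (relative powers, distance power
#'   already removed).
#' @param pupil_diameter_mm Pupil diameter in mm.
#' @param cfg An [optics_config()].
#' @return A [tf_curve()] of metric kind `"VS"`.
#' @export
tf_vs <- function(design, pupil_diameter_mm, cfg = optics_config()) {
  w <- reconstruct_wavefront(design, pupil_diameter_mm, cfg)
  n <- cfg$grid_n
  N <- as.integer(n * cfg$pad_factor)
  lambda_m <- cfg$wavelength_nm * 1e-9
  ax_m <- centered_axis_mm(n, w$pixel_mm) * 1e-3
  r2 <- outer(ax_m^2, ax_m^2, `+`)
  inside <- !is.na(w$opd_um)
  base_phase <- (2 * pi / lambda_m) * w$opd_um[inside] * 1e-6
  defocus_scale <- (2 * pi / lambda_m) * r2[inside] / 2
  J <- fft_embed_index(n, N)

  # CSF weights on the masked frequency pixels, computed once
  pitch <- freq_pitch_cpd(w$pixel_mm, cfg$wavelength_nm)
  k <- fft_offsets(N)
  freq <- pitch * sqrt(outer(k^2, k^2, `+`))
  wts <- csf_weights(freq, cfg$csf_params, cfg$max_freq_cpd)
  sel <- which(wts > 0)
  wsel <- wts[sel]

  eval_mtf_sum <- function(defocus_D) {
    block <- matrix(0 + 0i, n, n)
    block[inside] <- exp(1i * (base_phase - defocus_D * defocus_scale))
    field <- matrix(0 + 0i, N, N)
    field[J, J] <- block
    otf <- otf_from_field(field)
    sum(wsel * Mod(otf[sel]))
  }

  # diffraction-limited reference: flat wavefront, zero defocus
  dl_block <- matrix(0 + 0i, n, n)
  dl_block[inside] <- 1 + 0i
  dl_field <- matrix(0 + 0i, N, N)
  dl_field[J, J] <- dl_block
  denom <- sum(wsel * Mod(otf_from_field(dl_field)[sel]))

  vals <- vapply(cfg$focus_grid_D, eval_mtf_sum, numeric(1L)) / denom
  tf_curve(cfg$focus_grid_D, pmin(pmax(vals, 0), 1),
           metric_kind = "VS", pupil_diameter_mm = pupil_diameter_mm)
}
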