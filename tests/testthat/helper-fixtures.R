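# shared test fixtures: a reduced-resolution optics configuration keeps the
# unit tests fast; resolution-sensitive assertions use larger grids locally.

fast_cfg <- function(grid_n = 128L, focus_grid_D = seq(-2, 4, by = 0.05), ...) {
  optics_config(grid_n = grid_n, focus_grid_D = focus_grid_D, ...)
}

constant_design <- function(power_D, r = seq(0, 3, by = 0.05)) {
  design_profile(r, rep(power_D, length(r)))
}

constant_to_profile <- function(v) power_profile(seq(0, 3, by = 0.5), rep(v, 7))

# analytic diffraction-limited MTF of a circular aperture at normalized
# frequency nu = f / cutoff
airy_mtf <- function(nu) {
  nu <- pmin(pmax(nu, 0), 1)
  (2 / pi) * (acos(nu) - nu * sqrt(1 - nu^2))
}

incoherent_cutoff_cpd <- function(pupil_diameter_mm, wavelength_nm = 546) {
  (pupil_diameter_mm * 1e-3) / (wavelength_nm * 1e-9) * (pi / 180)
}
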