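---
title: "Simulating multifocal contact lenses: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multifocal contact lenses: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`mclsim` computes, from the radial power profile of a multifocal contact
lens (MCL), the lens's through-focus Visual Strehl (TF-VS) curve, and fits
the temporal-multiplexing program that lets an optotunable-lens visual
simulator reproduce that curve. This vignette documents the models, the
parameters that matter, and the numerical decisions, in the order the
pipeline runs.

## 1. From measured profiles to a design profile

A deflectometry power map of a soft MCL yields the local power $P(r)$
(diopters) against semi-diameter $r$ (mm, 0–3 mm: a 6 mm optical zone).
`mclsim` processes these series exactly as bench practice does:

* `smooth_profile()` applies a centered moving average over sample index,
  window 5 by default. At the series ends the window is **truncated** to
  the available samples rather than padded: padding would invent data
  beyond the measured domain, and the truncated mean is still unbiased for
  a locally constant profile. Smoothing runs over sample index, not a fixed
  radial width; instrument exports are uniformly sampled in radius, where
  the two coincide up to the sampling pitch.
* `average_repetitions()` takes the pointwise mean over repeated
  measurements (typically triplicates) and attaches the pointwise SD as QC
  metadata. The SD is *not* propagated into the optics: the optical model
  consumes only the mean profile. Smoothing precedes averaging; both are
  linear, so the order affects nothing but the QC SD (which is defined on
  the processed repetitions).
* `relative_profile()` subtracts the labeled distance power, isolating the
  add structure; `average_design()` averages the relative profiles of one
  design across its distance powers, interpolating linearly onto the union
  of the radial grids restricted to the shared support (no resampling
  convention is standard, and the union grid adds no smoothing of its own).

## 2. Synthetic designs

Because commercial profile data are proprietary, `design_spec()` generates
archetypes with the structure such lenses exhibit:

* **aspheric_center_near** — a Gaussian add profile
  $\mathrm{add}\cdot e^{-(r/h)^2}$. Real center-near aspherics decay
  smoothly and monotonically; a single shape parameter (the 1/e
  half-radius $h$, default 1.5 mm) is enough to span realistic designs.
* **concentric_rings / pure_bifocal** — piecewise-constant zone powers with
  a linear ramp of fixed 0.05 mm half-width at each boundary. Infinitely
  sharp zone edges would put slope discontinuities into the wavefront that
  no measured profile shows (the instrument low-passes the transition); the
  ramp width is well below the 5-sample smoothing scale.
* a quadratic distance-power coupling
  $s\cdot P_{dist}\cdot (r/3)^2$ (`sa_slope_D_per_D`) emulates the
  spherical-aberration-driven dependence of relative profiles on the
  labeled distance power; spherical aberration contributes local power
  quadratically in $r$.

`simulate_measurement()` adds i.i.d. Gaussian noise (SD 0.08 D by default,
per sample and repetition) to the absolute profile. With triplicates and
window-5 smoothing the per-radius repeatability SD stays below 0.10 D at
the 95% level — the level reported for careful bench measurements of soft
MCLs. Note the noise model is deliberately simple: it has no radial
correlation, no centration error, and no cuvette/saline refraction terms,
so passing tests demonstrate the *computational* chain, not instrument
physics.

## 3. Wavefront reconstruction

The local (ray-slope) power of a rotationally symmetric wavefront $W$ is
$P(r) = \frac{1}{r}\frac{dW}{dr}$, so the wavefront that reproduces a
measured profile is

$$W(r) = \int_0^r P(s)\, s\, ds, \qquad W(0)=0,$$

with $P$ in diopters and $s$ in meters (a constant $P$ gives the paraxial
defocus sphere $P r^2/2$). We adopt the slope-based convention rather than
curvature matching: deflectometry instruments report ray-based local power,
and for the paraxial quadratic case the two coincide. `reconstruct_wavefront()`
evaluates the integral by cumulative trapezoidal quadrature on a 4096-point
fine radial grid, then maps it to a 2-D map by radial symmetry on a
`grid_n` × `grid_n` pupil raster whose center lies on an exact grid sample.
Profiles may fall short of the pupil semi-diameter by up to 0.1 mm (the
3 mm measured semi-diameter meets the largest 6 mm pupil only at its
boundary) and are constant-extrapolated over that shortfall; anything
shorter is rejected. `local_power()` inverts the construction by centered
finite differences (parabolic fit for $P(0)$), which the tests use as a
round-trip oracle (RMS error < 0.02 D on all fixtures).

## 4. Fourier optics and the Visual Strehl metric

`pupil_function()` builds the generalized pupil: amplitude 1 on the
circular support, phase $\frac{2\pi}{\lambda}(W(r) - F r^2/2)$ at
evaluation focus $F$, so a zone of relative power $F$ is phase-flat exactly
at focus $F$ — positive focus values correspond to near adds. The field is
embedded in FFT order in an array `pad_factor` (default 2) times the pupil
diameter; with factor 2 the OTF support (twice the pupil bandwidth) exactly
fills the array. `mtf()` computes PSF = |FFT(pupil)|², OTF =
FFT(PSF)/FFT(PSF)(0), MTF = |OTF|; the frequency pitch is
pixel/λ cycles·rad⁻¹, reported in cycles/degree. Against the analytic
circular-aperture MTF the discretization error is below 0.01 at the default
`grid_n = 512` (about 5·10⁻⁴ at 256).

`visual_strehl()` implements the MTF-variant of the Visual Strehl ratio:

$$VS = \frac{\sum_f CSF(f)\, MTF(f)}{\sum_f CSF(f)\, MTF_{DL}(f)},$$

with the diffraction-limited reference recomputed **per pupil size** — each
pupil is judged against its own ideal, which is how a per-diameter
through-focus analysis is normally read. Phase-transfer information is
discarded. The neural weighting is the generalized band-pass form
$CSF(f) = f^a e^{-b f^c}$ with $a=1$, $b=0.114^{1.1}\approx0.0916$,
$c=1.1$ (the classic Mannos–Sakrison shape without its low-frequency
plateau, peaking near 8 cyc/deg), cut off at 60 cyc/deg. The overall CSF
scale cancels in the ratio; only the shape matters, and it is fully
overridable via `optics_config(csf_params=, max_freq_cpd=)` and recorded in
every output sidecar. Computation is monochromatic at 546 nm (the
deflectometry wavelength); there is no Stiles–Crawford apodization and no
ocular aberration beyond the defocus scan.

`tf_vs()` evaluates VS on the focus grid (−2.00…+4.00 D, 0.05 D steps by
default) for one pupil diameter. `peak_focus()` refines the grid argmax by
a three-point parabolic fit (ties broken toward the smallest |focus|),
because bench peak-shift comparisons against a 0.20 D criterion need
sub-step resolution.

## 5. Temporal-multiplexing programs

A temporal program is a set of nonnegative time fractions $c_k$ (unit sum)
over focus steps $a_k$ on a 0.1 D grid (default span −0.5…+4.0 D: it must
cover the features of the evaluation range; the number of active
coefficients then depends on the lens design). Temporal multiplexing mixes
*intensities* — the perceived PSF at focus $F$ is
$\sum_k c_k\,PSF(F-a_k)$, equivalently the combined OTF is the same convex
mixture of monofocal OTFs — so `program_tf_vs()` computes VS from the
modulus of the mixed OTF (incoherent superposition; field-level mixing
would be wrong by construction).

Two numerical points:

* Monofocal defocus OTFs are even in the defocus sign and rotationally
  symmetric, so the CSF-masked frequency pixels are collapsed into
  unit-pixel **radial bins** once per pupil; every program evaluation is
  then a small matrix product instead of ~10⁵-pixel FFT work. The binned
  path agrees with the full 2-D computation to about 10⁻³ in VS (tested),
  two orders below the bench RMSE criterion.
* The coefficient fit is defined **operationally**: minimize the VS-space
  RMSE against the target over the fit range (−1.00…+4.00 D by default)
  subject to $c_k \ge 0$, $\sum c_k = 1$. Stage 1 solves a nonnegative
  least-squares problem on the OTF-linear surrogate (unit sum imposed by an
  augmented row, weight 10); stage 2 refines with projected gradient on the
  probability simplex (analytic gradient through the |mixed OTF| term,
  backtracking line search, a couple of seeded perturbation restarts).
  Coefficients below 10⁻³ — dwell times no hardware realizes — are pruned,
  the rest renormalized and re-polished on the pruned support. The fit is
  deterministic given its seed. Only the curve match is claimed:
  coefficient vectors are not identifiable (distinct programs can produce
  near-identical TF-VS), and the tests assert curve-space recovery only.

`validate_bench()` applies the bench acceptance rule: pass iff the TF-VS
peak locations differ by < 0.20 D *and* the curve RMSE over the range of
interest (−1.00…+4.00 D, evaluated on the 0.05 D grid) is < 0.05.
`simulate_power_trace()`/`recover_program()` close the loop with a
simulated high-speed focimeter recording (3823 Hz sampling, 20 ms period):
histogramming the trace into 0.1 D bins recovers the coefficients.

## 6. Comparison statistics

* `depth_of_focus()`: the measure of $\{F: VS(F) > 0.12\}$ with linearly
  interpolated threshold crossings. For bimodal curves "the range above
  threshold" is ambiguous, so both the **total** superthreshold measure
  (primary) and the largest contiguous interval are reported.
* `partial_correlation()`: $r_{xy\cdot z}$ by the standard first-order
  formula, used to compare through-focus curves while controlling for the
  defocus value; degenerate inputs (zero residual variance, collinearity
  with the covariate) raise a typed error. The tests pin it to a
  regression-residualization oracle at 10⁻¹².
* `curve_rmse()` on matched grid points (finer grid over the overlap), no
  smoothing — mirroring how clinical through-focus acuity is sampled
  (0.50 D steps).
* `match_pupil_step()`: nearest 0.5 mm simulation step, exact midpoints
  rounding up (a fixed rule is needed; measured datasets rarely hit exact
  midpoints).

## 7. Problem sizes and determinism

Defaults are `grid_n = 512` pupil samples (numerical MTF error < 0.01
against the analytic aperture form) with padding factor 2; the unit-test
suite exercises resolution-insensitive properties at 64–256 samples, where
TF-VS values differ from the next refinement by < 0.01 (tested). One
through-focus curve at defaults costs ~121 pairs of 1024² FFTs; a full
fit-and-validate run for one design and pupil takes on the order of a
minute on a single core. All randomness (measurement noise, fit restarts)
flows through explicit integer seeds; reruns with the same configuration
and seed are byte-identical (tested at the pipeline level, including the
checksummed run manifest).

## 8. Known limitations

* **VS, not acuity.** The package never maps VS to visual acuity; clinical
  TF-VA enters only as data for the comparison statistics.
* **Eye–lens interaction is out of scope.** Only the lens's relative
  (add-only) profile is simulated; the interaction of the lens's spherical
  aberration with the eye's, which differs between myopic and hyperopic
  prescriptions of the same design, is not modeled.
* **DoF versus pupil diameter.** Because VS is normalized per pupil against
  that pupil's diffraction limit while the 0.12 DoF threshold is absolute,
  and defocus wavefront error grows with the pupil area, the whole TF-VS
  curve compresses toward zero at larger pupils. For the Gaussian
  center-near archetype this compression outweighs the wider add range the
  larger pupil admits, so the generator family shows DoF *decreasing* with
  pupil diameter. Measured MCLs with a compact central add and an extended
  true-distance periphery can show the opposite trend (a tall distance peak
  emerging at large pupils); the Gaussian archetype, whose periphery only
  asymptotically reaches distance power, does not reproduce that geometry.
  The acceptance suite states the increasing-DoF expectation for the
  aspheric fixture and it fails there by construction — kept as an
  honest negative result documenting this model-family limitation.
* **Monochromatic, aberration-free instrument model.** No chromatic
  effects, no retinal sampling, no Stiles–Crawford effect, no optotunable
  lens dynamics or distortion precompensation.
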