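# mclsim

Through-focus Visual Strehl simulation of multifocal contact lenses, and
temporal-multiplexing programs that reproduce them on optotunable-lens
visual simulators.

## The problem

Multifocal contact lenses (MCLs) correct presbyopia by distributing optical
power across the lens radius — smoothly decaying center-near aspherics, or
concentric rings with discrete power steps. Fitting them in the clinic is
trial-and-error; a visual simulator can instead *preview* a lens design by
cycling an optotunable lens through focus states faster than flicker fusion,
so the patient perceives the time-averaged multifocal point-spread function.
`mclsim` implements the computational chain that turns an in-vitro power
profile of a lens into the temporal program that emulates it:

1. **Profiles** — radial power profiles P(r) (diopters vs semi-diameter over
   a 6 mm optical zone) are smoothed with a 5-sample moving average,
   averaged over repetitions, reduced to the *relative* (add-only) profile
   by subtracting the labeled distance power, and averaged across distance
   powers into one design-level profile.
2. **Fourier optics** — the rotationally symmetric wavefront
   W(r) = ∫₀ʳ P(s)·s ds is reconstructed from the relative profile, and the
   through-focus Visual Strehl (TF-VS) is computed at each focus F on a
   −2.00…+4.00 D grid (0.05 D steps) for pupil diameters 3–5 mm:

   VS(F) = Σ_f CSF(f)·MTF_F(f) / Σ_f CSF(f)·MTF_DL(f),

   the contrast-sensitivity-weighted volume under the MTF, normalized by
   the diffraction-limited MTF of the same pupil (monochromatic, 546 nm).
3. **Temporal program** — nonnegative time coefficients c_k on a 0.1 D step
   grid a_k are fitted so that the TF-VS of the mixture OTF
   Σ_k c_k·OTF(F − a_k) matches the lens's TF-VS (NNLS initialization on
   the OTF-linear model, then projected-gradient refinement of the true
   VS-space RMSE on the simplex).
4. **Bench validation** — a simulation passes if its TF-VS peak is within
   0.20 D of the target and the RMSE over −1.00…+4.00 D is below 0.05.
5. **Comparison statistics** — depth of focus (extent with VS > 0.12),
   partial correlation r\_xy·z controlling for defocus, curve RMSE, and
   pupil matching to the 0.5 mm simulation grid.

A synthetic design generator (`design_spec()`, `simulate_measurement()`)
produces aspheric center-near, concentric-ring, bifocal and monofocal
archetypes with realistic repetition noise, so the whole pipeline is
testable without proprietary lens data.

## Worked example

```r
library(mclsim)

# a synthetic center-near aspheric lens: add 1.5 D, Gaussian half-radius
# 1.5 mm, labeled distance power -2 D, three noisy measurement repetitions
spec <- design_spec("aspheric_center_near", add_D = 1.5,
                    params = list(half_radius_mm = 1.5), distance_power_D = -2)
reps <- simulate_measurement(spec, n_reps = 3, seed = 7)

# smooth (window 5), average repetitions, subtract distance power
avg    <- relative_profile(average_repetitions(lapply(reps, smooth_profile)))
design <- average_design(list(avg))
design
#> <design_profile> synthetic_aspheric_center_near / 1.50D add (averaged over 1 distance powers)
#>   301 samples, r in [0.00, 3.00] mm, relative power in [-0.03, +1.56] D

cfg    <- optics_config()          # 546 nm, -2..+4 D in 0.05 D steps
target <- tf_vs(design, 4, cfg)    # through-focus Visual Strehl, 4 mm pupil
target
#> <tf_curve> VS, 4.0 mm pupil, 121 points on [-2.00, 4.00] D
#>   peak 0.480 at +0.62 D
depth_of_focus(target)
#> <dof> total 1.87 D (largest contiguous 1.87 D, 1 segment)

# fit the temporal-multiplexing program and validate it on the bench criteria
prog <- fit_temporal_coefficients(target, 4, cfg, seed = 42)
prog
#> <temporal_program> 46 steps on [-0.5, 4.0] D, 11 active
#>   fitted: RMSE 0.0327 over [-1.00, 4.00] D
sim <- program_tf_vs(prog, 4, cfg)
validate_bench(target, sim)
#> <bench_report> peak shift 0.007 D, RMSE 0.0327 over [-1.00, 4.00] D: PASSED
```

The TF-VS peak at +0.62 D (between distance, 0 D, and the 1.5 D add)
reflects the simultaneous-vision compromise of the center-near design; the
1.87 D depth of focus is the focus extent with VS > 0.12. The fitted
11-state program reproduces the lens's through-focus behavior well inside
both bench criteria.

`run_pipeline()` chains all stages over several input files and pupil
diameters and writes every artifact (design profile, TF-VS curves,
programs, bench reports) with a checksummed run manifest. A thin CLI over
the same functions ships in `inst/cli/mclsim`
(`synth | tfvs | fit-program | validate | compare | run`).

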