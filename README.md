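# aidar — single-breath nanoparticle lung deposition analysis

`aidar` analyzes single-breath measurements of nanoparticle deposition in
the distal lung (the airspace dimension assessment, AiDA, family of
measurements). A subject exhales to residual volume, inhales monodisperse
nanoparticles (22–100 nm) to total lung capacity, holds breath for a
controlled 3–20 s, and exhales into a sample collector; a 0.3 L slice from
about 1.2–1.5 L volumetric lung depth is counted with a condensation
particle counter. The package is for aerosol scientists and respiratory
physiologists who need to turn the raw traces of such an instrument —
100 Hz pneumotachograph flow, 1 Hz particle counts — into loss-corrected
recoveries and subject-level decay parameters, and for anyone building or
validating such an instrument with simulated data.

## The model

The measurand is the particle recovery

    R = (C_sample / C_reservoir) / R_instrument

where `C_reservoir` and `C_sample` are mean number concentrations of the
inhaled and exhaled aerosol (20 s and 10 s averaging windows) and
`R_instrument` is the penetration efficiency of the apparatus, modeled
semi-empirically as

    R_instrument = A · exp(−b · D · t_instrument)

with `D` the slip-corrected Stokes–Einstein diffusion coefficient,
`t_instrument` the summed passage time of the instrument dead volume on the
inhalation and exhalation legs, and empirical constants `A` (≈ 1.00) and
`b` (≈ 2.63·10⁷ m⁻²) fitted from syringe calibration runs. Because
deposition of sub-100 nm particles during a breath hold is pure Brownian
diffusion, recovery declines exponentially with the residence time `t` of
the aerosol in the lung, `R(t) = R₀·exp(−t/τ)`; the decay time
`τ ≈ r²/(π²D)` probes the effective distal airspace radius `r`. Recoveries
are compared across subjects after normalization to a 10 s residence time.

Alongside the analysis chain the package provides the transport physics
(Cunningham slip, Stokes–Einstein diffusion, sphere and laminar-tube
deposition kernels), a simplified forward deposition simulator
(`simulate_recovery()`), and a synthetic-data generator
(`generate_session()`) that emulates the instrument — maneuver flow traces,
Poisson counting noise, instrument losses, between-repeat variability —
with full ground truth for validation.

## Worked example

```r
library(aidar)

# calibrate the instrument loss model from a (synthetic) syringe run
instrument <- loss_model(A = 1.00, b = 2.63e7)
records <- generate_calibration_run(instrument, noise_cv = 0.005, seed = 1)
fit <- fit_loss_model(records)
fit
#> Instrument loss model: R_instrument = A exp(-b D t)
#>   A = 1.001, b = 2.623e+07 m^-2 (D at 308.15 K)
#>   calibration: n = 72, residual RMS = 4.20e-03, Pearson r = 0.9997

# simulate and analyze a subject session: 75 nm particles, six breath-hold
# times, three repeats each, true decay law R(t) = 0.30 exp(-t / 8 s)
subject <- subject_profile(r0_tau = list(`75` = c(0.30, 8)), repeat_sd = 0.005)
session <- generate_session(subject,
                            conditions = expand.grid(size_nm = 75,
                                                     hold_s = c(3, 5, 7, 10, 15, 20)),
                            seed = 17)
analysis <- analyze_session(session, session$loss)
analysis
#> Session analysis: 18 measurements (0 rejected)
#>   75 nm: R0 = 0.315, tau = 7.62 s, R(10 s) = 0.0849
head(analysis$summary)
#>   size_nm hold_s     mean_R        sd_R n sd_flagged
#> 1      75      3 0.16424824 0.005041186 3      FALSE
#> 2      75      5 0.12374316 0.004211639 3      FALSE
#> 3      75      7 0.09590852 0.005003229 3      FALSE
#> 4      75     10 0.06629632 0.003269348 3      FALSE
#> 5      75     15 0.03215979 0.002265154 3      FALSE
#> 6      75     20 0.01862632 0.001026095 3      FALSE
```

The calibration recovers the generating constants (`A` = 1.001 vs 1.00,
`b` = 2.623e7 vs 2.63e7 m⁻²) with the near-unity observed-vs-fitted
correlation expected at counting-statistics noise. The session analysis
runs every measurement through phase detection, residence-time computation
and loss correction: the fitted decay time (7.62 s vs the true 8 s) and the
10 s-normalized recovery (0.0849 vs the true 0.30·e^(−10/8) = 0.0859) come
back within the repeatability of the measurement, and the per-condition
repeat SDs sit in the 0.002–0.008 band typical of the physical instrument.

File-based workflows use `session_simulate()` / `session_calibrate()` /
`session_analyze()` (CSV traces with JSON sidecars, JSON manifests, tidy
CSV results); `inst/cli/aida.R` wraps them for the shell.

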