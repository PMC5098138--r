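---
title: "Single-breath nanoparticle recovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-breath nanoparticle recovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidar)
```

## The measurement

A subject exhales to residual volume (RV), inhales a monodisperse
nanoparticle aerosol (22–100 nm) to total lung capacity (TLC), holds breath
for a controlled 3–20 s, and exhales into a sample collector. A slice of the
collected air, drawn from a defined volumetric lung depth (about 1.2–1.5 L
with the default volumes), is counted with a condensation particle counter
(CPC) and compared with the inhaled reservoir concentration. The measurand
is the particle *recovery*

$$ R \;=\; \frac{C_\mathrm{sample} / C_\mathrm{reservoir}}{R_\mathrm{instrument}}, $$

the fraction of inhaled particles that re-emerge from the distal lung after
correcting for diffusional losses in the mouthpiece, tubing and valves.
Because particles in this size range deposit essentially only by Brownian
diffusion, $R$ declines (asymptotically) exponentially with the residence
time of the aerosol in the lung, and the decay time is a probe of distal
airspace dimensions: for diffusion in a closed cavity of effective radius
$r$, the remaining airborne fraction is

$$ f(t) \;=\; \frac{6}{\pi^2}\sum_{n\ge 1} n^{-2}
   \exp\!\left(-\frac{n^2\pi^2 D t}{r^2}\right), $$

whose dominant mode has decay time $\tau = r^2/(\pi^2 D)$. The package
implements the full chain from raw traces to $R$, the exponential
recovery-vs-residence-time fit $R(t) = R_0 e^{-t/\tau}$, and the recovery
normalized to a 10 s reference residence time, plus a forward simulator and
a synthetic-data generator that stand in for the physical instrument and
subjects.

## Transport physics

The diffusion coefficient is slip-corrected Stokes–Einstein,
$D = k_B T\, C_c / (3\pi\mu d)$, with the Cunningham slip factor in the
Davies parameterization $C_c = 1 + Kn\,(1.257 + 0.400\,e^{-1.100/Kn})$,
$Kn = 2\lambda/d$. Viscosity and mean free path follow Sutherland-type
temperature scaling anchored at 23 °C and 101.325 kPa
($\mu = 1.83245\times10^{-5}$ Pa s, $\lambda = 67.3$ nm). Davies'
coefficient set is the common aerosol-science default; any self-consistent
set changes sub-100 nm $D$ by well under 1%.

Two temperatures matter and are deliberately distinct defaults:

* **35 °C** (`gas_conditions()`) — the instrument's heated valve box, used
  for the instrument loss model and its calibration.
* **37 °C** (`gas_conditions(temperature = 310.15)`) — body temperature,
  used for residence-time deposition in the lung and by the forward
  simulator.

Both are explicit arguments everywhere; nothing is hard-wired.

Diffusional penetration of a laminar tube uses the Gormley–Kennedy solution
parameterized by $\mu' = \pi D L/Q$: the four-term eigenvalue series for
$\mu' \ge 0.02$ and the short-tube expansion below. The two branches agree
at the switch point to within $2\times10^{-4}$, and the test suite checks
both branches against an independent Crank–Nicolson solution of the Graetz
convection–diffusion problem to within $10^{-3}$. The sphere series is
truncated when the next term falls below $10^{-12}$ (at most $10^4$ terms);
it is checked against a $10^5$-walker Monte-Carlo random walk with
Brownian-bridge wall absorption.

## The instrument loss model

Penetration of the apparatus is modeled semi-empirically as

$$ R_\mathrm{instrument} = A \exp(-b\,D\,t_\mathrm{instrument}), $$

with dimensionless pre-factor $A$ and exponent coefficient $b$ (m⁻²). This
form is the natural one for diffusional depletion — exponential in the
diffusion rate and the time spent in the apparatus — and a units/magnitude
check supports it: with the calibrated values $A = 1.00$ and
$b = 2.63\times10^{7}$ m⁻² the model reproduces penetrations of 0.948
(100 nm) down to 0.0781 (22 nm) at passage times of 2.8–7.9 s, exactly the
transit times implied by the instrument dead volume and realistic breathing
flows. Folding the end-inspiratory volume $V_i$ into the exponent instead
fails this check by orders of magnitude, so $V_i$ is computed by the
maneuver module for reporting and QC only.

The passage time sums the two transits of the instrument dead volume,
$t_\mathrm{instrument} = V_\mathrm{dead}/\bar Q_\mathrm{in} +
V_\mathrm{dead}/\bar Q_\mathrm{ex}$, with phase-mean flows. The dead volume
defaults to 0.3 L — the combined mouthpiece/flow-meter/valve estimate — and
is configurable, as the split between instrument and anatomical dead space
is not separately observable from the traces.

Calibration (`fit_loss_model()`) is nonlinear least squares in linear
penetration space by default, with a log-space option. Linear space is
preferred because counting noise is roughly proportional to the measured
penetration and a log-space fit would inflate the weight of the smallest,
least certain penetrations (the 22 nm, long-transit records, where losses
exceed 90%). Starting values come from the log-linear regression. The
design must span at least two particle sizes and two passage times —
otherwise only the product $A e^{-bDt}$ is identified and the fit aborts
with a rank-deficiency error. Observed penetrations above 1.02 are flagged
(counting drift), above 1.1 rejected.

## Maneuver processing

`detect_phases()` finds the breath hold as a sustained near-zero-flow
plateau: |flow| < 0.05 L/s on a 50 ms smoothed trace, sustained ≥ 0.3 s,
with 0.02 L/s exit hysteresis. The thresholds sit well below physiological
maneuver flows (≳ 1 L/s) and well above pneumotachograph noise
(≈ 0.02 L/s SD); smoothing makes a false plateau break at 100 Hz
astronomically unlikely. Phases II and I are refined to the flow zero
crossings bounding the inhalation; valve-event timestamps embedded in the
trace override flow-derived estimates whenever present.

Definitions, all evaluated on the trapezoidal cumulative volume integral:

* $V_i$ — inspired volume over II→III (RV to TLC), i.e. inspiratory vital
  capacity. Absolute lung volume is unobservable from a flow trace alone,
  so the inspired volume is the only trace-supported reading.
* **Residence time** — from the moment half of $V_i$ has been inhaled to
  the moment half of the collector volume has been exhaled. It always
  exceeds the breath-hold time and is the abscissa of all recovery fits.
* **Sample depth window** — the analyzed slice is drawn from the collector
  inlet end, i.e. the last-exhaled, deepest air (last in, first sampled):
  depth $[\,V_\mathrm{col} - V_\mathrm{analyzed} + V_\mathrm{dead},\;
  V_\mathrm{col} + V_\mathrm{dead}\,]$. With the defaults (1.2 L collector,
  0.3 L slice, 0.3 L dead space) this is the 1.2–1.5 L window. Only this
  reading reproduces that window; sampling from the outlet end would probe
  the shallowest air instead.

Volumes are reported at instrument conditions; no BTPS correction is
applied (none is observable without additional inputs; the recovery ratio
is unaffected).

## Recovery, aggregation, curve fitting

Concentration means use a 20 s reservoir window (ending when the aerosol
valve opens) and a 10 s sample window (starting when collector sampling
begins, 2 s after valve closure for line transit). Uncertainties are exact
Poisson: over a window of length $T$ at counter flow $v$ (1 L/min), the SD
of the mean is $\sqrt{\bar C/(vT)}$.

`compute_recovery()` enforces the identity
$R_\mathrm{raw} = R \cdot R_\mathrm{instrument}$ exactly and flags:
`low_confidence` when $R_\mathrm{instrument} < 0.1$ (corrections for 22 nm
particles at long transits are dominated by the instrument, not the lung),
`qc_fail` when $R > 1.2$. Reservoir stability QC fails when the CV or the
relative linear drift over the measurement exceeds 5% (configurable); the
recovery is exactly invariant to the absolute concentration, so stability,
not level, is what matters.

Repeats of one condition aggregate to mean and SD; an SD above 0.011 — the
worst repeatability observed with the reference instrument — is flagged.
`fit_recovery_curve()` fits $R_0 e^{-t/\tau}$ by least squares in linear
space (inverse-variance weights optional, from the counting SDs), excludes
non-positive recoveries with a warning, and refuses designs without at
least 3 points over 2 distinct residence times. Normalization evaluates the
fitted curve at 10 s by default — inside the residence-time range of every
standard session, so it is an interpolation, not an extrapolation. The
per-subject exponential is the parameterization used for time
normalization; over 3–20 s holds the simulator confirms $\ln R$ linear in
residence time to $R^2 > 0.999$, so the choice of parameterization is not
limiting.

## The forward simulator

`simulate_recovery()` composes the two kernels:

$$ R_\mathrm{pred} = P_\mathrm{tube}(Q_\mathrm{in})\;
   f_\mathrm{sphere}(t_\mathrm{res})\; P_\mathrm{tube}(Q_\mathrm{ex}), $$

with Gormley–Kennedy penetration per conducting generation (per-tube flow =
total flow / tube count) and the sphere kernel over the maneuver residence
time. The default conducting path is a symmetric Weibel-type table,
generations 0–13; everything distal — terminal bronchioles onward — is
subsumed into the spherical airspace compartment, which is the natural
reading at full inflation where the respiratory zone dominates both volume
and deposition. The airspace radius (default 0.3 mm, a typical acinar
airspace scale at TLC) is the subject-level parameter: radii of roughly
0.22–0.43 mm reproduce 10 s-normalized recoveries of 0.14–0.44 for 100 nm
particles, the span observed across healthy adults. The simulator is an
explicitly simplified stand-in for multi-path dosimetry models: symmetric,
diffusion-only, no lobar asymmetry, intended for qualitative agreement and
for generating synthetic cohorts, not for replicating any particular
reference model's numbers.

The residence time during inhalation and exhalation is counted in full
toward the sphere kernel while the aerosol also transits the conducting
tubes; this double-counts a fraction of a second of distal exposure.
The effect is a small, flow-independent bias absorbed into the effective
radius, and is one reason the radius is "effective" rather than anatomical.

## The synthetic-data generator

`generate_session()` emulates, per measurement:

* a 100 Hz flow trace with half-sine segments (two tidal cycles, exhalation
  to RV at 0.75 L/s mean, commanded inhalation, hold, full exhalation),
  Gaussian sensor noise of 0.02 L/s SD, and valve events embedded at the
  realized switching times. The realized hold deviates from the commanded
  duration by up to ±100 ms, the valve timing precision of the reference
  hardware;
* 1 Hz CPC traces with exact Poisson counting at 1 L/min (16.7 cm³ per
  sample), reservoir mean 4000 cm⁻³ by default (the study range was
  1000–10000 cm⁻³, typically 3000–6000), optional linear drift (default 0:
  the instrument maintains a stable reservoir);
* a true recovery from either the prescribed per-size $(R_0, \tau)$ law or
  the forward simulator, evaluated at the closed-form true residence time,
  degraded by the true instrument penetration at the true passage time, and
  by multiplicative lognormal between-repeat variability scaled to an
  absolute SD of 0.005 on $R$ — the midpoint of the instrument's observed
  0.002–0.008 repeatability band, which is an absolute band across
  recoveries spanning an order of magnitude.

Ground truth (true $R$, residence time, instrument penetration, seeds) is
stored separately and never read by the analysis path. Default study grid:
4 sizes × 6 holds × 3 repeats = 72 measurements.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: cardiogenic oscillations and irregular
breathing (real plateaus are not flat), mixing with residual air at the
sample depth, airway-geometry heterogeneity between lung regions,
hygroscopic growth (the reference particles are hydrophobic), electrostatic
deposition of the singly charged particles, and CPC drift or coincidence
effects. Phase detection is exercised only on maneuvers of the commanded
shape plus stationary noise.

## Numerical and testing choices

Fits use Levenberg–Marquardt (`minpack.lm`) with analytic-free residuals,
log-linear starting values, and box constraints keeping $A \in (0, 1.5]$,
$b > 0$, $\tau > 0$. Noise-free generator/fitter round trips recover
parameters to relative error $< 10^{-6}$; noisy recovery is cross-checked
against brute-force grid searches. The test problem sizes — 72-record
calibrations, 18-measurement sessions, $10^5$ Monte-Carlo walkers at three
dimensionless times, five Graetz comparisons — were chosen so the full
suite completes in about a minute while keeping Monte-Carlo standard errors
($\approx 1.5\times10^{-3}$) small against the agreement tolerances.

## Known limitations

* The recovery is not a deposition fraction: $1 - R$ confounds deposition
  with any residual-air mixing; the RV→TLC maneuver minimizes but does not
  eliminate the latter.
* The loss model treats both transits with a single $(A, b)$ pair; leg
  asymmetries (e.g. humidity on exhalation) fold into the calibration.
* The forward simulator's airspace radius is effective, not anatomical, and
  the conducting/distal split at generation 13 is a modeling choice; both
  are configurable.
* Flow-derived phase V (collector closure) requires either a valve event or
  a known collector volume; with neither, the end of exhalation is used and
  the collector volume is inferred from the trace.
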