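---
title: "A physiomechanical model of the energy cost of shallow-water walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physiomechanical model of the energy cost of shallow-water walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquacot)
```

## The model

Walking upright in a pool differs from dry-land walking through two forces:
buoyancy, which supports part of the body weight and turns immersion into a
simulated hypogravity condition, and hydrodynamic drag, which resists every
submerged segment's motion. `aquacot` predicts the net metabolic cost of
transport (COT, J per kg per metre) of shallow-water walking from the
mechanical work done against these two forces over a stride:

* **Drag work.** Each lower-limb segment and the trunk is a conic frustum
  (radii from measured circumferences, `r = c / 2π`), cut into thin
  transverse strips. Strip theory treats each strip as an independent 2-D
  cross-flow element: the pressure drag on a strip is
  `F = ½ ρ C_d A v_n |v_n|`, where `v_n` is the velocity component normal
  to the segment axis in the sagittal plane and `A = 2 r ℓ` times the
  immersed fraction of the strip. Frictional and wave drag are neglected:
  at the Reynolds numbers of walking in water (10^4–10^6, reported per run)
  pressure drag dominates. Summing strips and segments gives the net
  horizontal drag at each video frame; the stride-representative drag force
  `DrF` is the time average of its magnitude over the stride, reported
  separately for the contact and swing phases and combined as a
  duration-weighted mean. The drag work per stride is `W_D = DrF · SL`,
  with `SL` the stride length.
* **Vertical work.** Over a full stride the mean vertical ground reaction
  force equals the supported weight, so immersion reduces it to
  `GRF_v = w · m · g`, where the weight-bearing fraction `w` comes from a
  piecewise-linear table of apparent weight against immersion depth as a
  fraction of stature. The centre of mass rides a compass-gait arc over the
  stance leg: it rises `COM_vert = L_leg (1 − cos(½ L_sc / L_leg))` during
  each single-support phase of forward displacement `L_sc`, and the work to
  lift it twice per stride is `W_v = GRF_v · 2 · COM_vert`.
* **Cost.** Total stride work `W_Aqua = W_D + W_v` converts to predicted
  cost via an assumed muscle efficiency of 0.25:
  `COT_pred = W_Aqua / (SL · m · 0.25)`. Concentric actions dominate in
  water (buoyancy and drag suppress eccentric braking), which motivates the
  single efficiency value; it is an argument everywhere it appears.

Measured cost comes from indirect calorimetry: gross metabolic power is the
windowed mean oxygen uptake times the energy equivalent of oxygen
(`16.04 + 4.94·RER` J/ml by default; Brockway's `16.58 + 4.51·RER` is
selectable), net power subtracts the at-rest gross power at the same depth,
and COT is net power over speed.

The response of measured COT to speed `s` and immersion depth `d` is
summarised by a full quadratic surface,
`COT = a_ss s² + a_dd d² + a_sd s d + a_s s + a_d d + a_0`,
fit by ordinary least squares (`fit_surface()`); `study_surface()` carries
the published coefficient set for healthy adult men over speeds 0.2–0.8 m/s
and depths 0.5–1.3 m, with its 95% CIs. The surface is indefinite
(`4 a_ss a_dd < a_sd²`, a saddle), so its extrema over the tested box are
found among the interior critical point, the four edge vertices and the
four corners — all closed-form. Iso-cost speeds between cost–speed curves
(per-depth fits, or reference swimming/dry-land equations supplied as
quadratic coefficient sets in JSON) are roots of the quadratic difference,
solved in closed form with a residual check.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_strips` | 20 | — | The drag integrand varies smoothly along a segment; the midpoint rule is exact for the linear diameter integrand, and `DrF` changes < 1% between 20 and 40 strips on generated gait. |
| `cutoff` | 4.5 | Hz | Midpoint of the 4–5 Hz band conventional for slow-walking kinematics; applied zero-phase (forward–backward 2nd-order Butterworth) so events are not delayed. |
| `density` | 995.7 | kg/m³ | Water at 31–32 °C (thermoneutral pool). |
| `cd_limb`, `cd_trunk` | 1.0 | — | Circular cylinder in turbulent cross-flow; configurable per segment class. |
| `kinematic_viscosity` | 7.7e−7 | m²/s | Water at ~32 °C; Reynolds reporting only. |
| `efficiency` | 0.25 | — | Concentric-dominant muscle work in water. |
| contact thresholds | 0.02 m, 0.05 m/s | | Calcaneus height above floor and horizontal speed bounds defining foot contact; standard for slow walking, exposed as arguments. |
| weight-bearing table | 5 nodes | — | (0, 1.00), (0.28, 0.88), (0.48, 0.58), (0.63, 0.48), (0.73, 0.33) in depth fraction of stature; replaceable by a CSV of literature values. |
| calorimetry equation | Garby–Åstrup | | The choice of energy-equivalent equation is genuinely open; both common linear forms are provided and the default is stated rather than presumed. |

## What the synthetic cohort emulates — and what it does not

`cohort_config()` defaults encode the study conditions: nine adults (mass
77.1 ± 9.8 kg truncated at ±3 SD, stature 1.78 ± 0.04 m), four immersion
depths (0.5, 0.85, 1.12, 1.3 m), four nominal speeds (0.2–0.8 m/s), five
analysed strides per condition, 60 Hz sagittal markers with 3 mm additive
Gaussian noise (the order of manual video digitisation error), and
breath-by-breath gas exchange with 5% multiplicative lognormal noise.
Landmark standing heights are fixed fractions of stature chosen to
reproduce the study's depth fractions (knee 28%, trochanter 48%, umbilicus
63%, xiphoid 73%); circumferences scale with `sqrt(mass/stature)` relative
to reference adult girths. Stride length follows `SL = 0.5 + 0.5·speed`
(0.6–0.9 m over the tested range, slow-walking values), cadence is
`speed/SL`, stance occupies 60% of the cycle, and the trochanter advances
at exactly the requested speed, so stride detection has an exact ground
truth. The knee is placed by two-link inverse kinematics between hip and
ankle; the contralateral leg is the digitised leg phase-shifted by half a
stride. Metabolic records are generated by inverting the calorimetry
equations at breath-wise RER drawn uniformly in 0.79–0.87, so zero-noise
records invert exactly (the energy equivalent is linear in RER, hence
window means commute with the conversion).

The generator is deliberately simple where simplicity does not matter
downstream: the trunk translates at constant height, the foot is rigid, and
joint-angle waveforms are smooth analytic profiles rather than recorded
human trajectories. Only stride-integrated quantities (SL, `L_sc`, segment
velocities, immersion geometry) feed the model, so passing tests show the
*pipeline* is correct — they do not show that real human kinematics are
reproduced, and absolute drag levels on real swimmers' data will differ
from the generator's (see limitations).

## Numerical choices

* **Zero-phase filtering.** `signal::filtfilt` starts from zero state, so
  the series is padded by odd reflection (about six time constants of the
  cutoff) before the forward–backward pass and trimmed after; a constant
  series passes through unchanged to 1e−9.
* **Edge frames.** Velocities are central differences; the first and last
  detected strides are excluded from analysis, and the contralateral
  half-stride shift folds by whole stride periods so that it never sources
  frames from the series edges.
* **Partial immersion.** A strip crossing the waterline contributes the
  immersed fraction of its length, avoiding discretisation jumps as
  segments pierce the surface.
* **Stride events.** Contact onsets closer than half the median stride
  spacing are treated as one event (the last of the cluster), which makes
  detection robust to marker noise blips.
* **Degenerate fits.** Zero-residual surface fits are legal (their CIs are
  degenerate); rank-deficient designs (fewer than three distinct speeds or
  depths) are rejected with an explicit error.
* **Extrapolation.** Surface evaluation outside the fit box warns unless
  explicitly allowed; reference curves warn outside their declared validity
  range (the swimming equation in particular is an extrapolation below
  ~0.96 m/s). Weight-bearing depth fractions up to 1.5 percentage points
  beyond the last table node extrapolate silently (within the study's
  spread of depth fractions); larger overshoots warn.

## Design decisions that were genuinely open

* **What kind of quantity is `DrF`.** Summing strip forces over time has
  units of N·frames; multiplying by stride length to get work requires a
  stride-representative force in newtons. We define `DrF` as the
  time-average over the stride of the magnitude of the *net* horizontal
  drag, computed per phase and duration-weighted (equal to the whole-stride
  average). A `time_sum` (impulse-like) aggregation is exposed as an
  option. Under the net-sum convention opposing-limb forces partially
  cancel, so absolute `DrF` levels are lower than under a
  sum-of-magnitudes convention; conclusions that rest on scaling
  (quadratic in speed, monotone in depth) are unaffected.
* **Foot drag.** Whether the foot belongs in the drag budget is not
  settled; it is included as a frustum by default and removable via
  `build_segment_model(include_foot = FALSE)`.
* **Weight-bearing table.** The default table is constructed from the
  landmark gravity equivalents at their mean depth fractions rather than
  from any single literature source, making the package self-contained; a
  CSV override is the intended route for literature values.
* **LOOCV unit and fitted component.** The leave-out unit is the
  participant (matching the bootstrap resampling unit and avoiding
  within-participant dependence); the refitted component is a linear
  calibration of measured on predicted cost, which is exactly the identity
  on noiseless data.
* **Mass sensitivity.** A ±10% mass perturbation by default touches only
  the cost denominator (apparent weight held fixed), the only convention
  under which the response is exactly inverse-proportional and mirrors the
  efficiency response; a propagate-to-`GRF_v` mode is provided.
* **Self-selected predictions.** The summary evaluates the surface at the
  cohort-mean self-selected speed per depth. Because the evaluator is
  vectorised, the alternative — evaluate at each participant's speed and
  average — is a one-liner; the two differ where the surface curves across
  the speed spread, and neither is presumed authoritative.
* **Fit speeds.** Surfaces are fit at nominal speeds by default; achieved
  speeds (the fastest target is typically not attained in deep water) can
  be substituted by passing them in the fit data.

## Problem sizes

The test suite exercises the full pipeline at 2–3 participants with 3
analysed strides per condition and the complete 9-participant cohort for
the end-to-end coefficient-recovery check; the bootstrap calibration check
runs 200 replicate cohorts at 1,000 resamples each. These sizes make the
default suite complete in well under a minute while keeping every check at
the study's own cohort geometry where it matters.

## Known limitations

* Absolute drag magnitudes depend on the `DrF` aggregation convention and
  on segment drag coefficients that are configuration, not measurement.
* The vertical-work term uses the stride-mean vertical load and a
  compass-gait arc; time-varying ground reaction waveforms and pendular
  energy recovery are outside the model.
* Added-mass (acceleration-reaction) forces, wave drag and skin friction
  are neglected.
* The percentile bootstrap interval for the prediction R², resampling nine
  participants, is slightly anti-conservative: in the suite's calibration
  simulation it covers a known population R² in about 89% of replicates
  rather than the nominal 95% — a small-cluster-count property of
  percentile intervals (the estimator itself is unbiased in the same
  simulation). Interpret the CI accordingly at this cohort size.
* The synthetic cohort validates computation, not physiology: no muscle
  coactivation, energy transfer between segments, or thermoregulatory
  effects are simulated.
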