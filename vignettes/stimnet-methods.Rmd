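---
title: "Models and methods behind stimnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stimnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimnet)
```

`stimnet` analyses how a graded neuromodulation intensity (four stimulation
levels, 0–3) shapes (a) spiral-drawing kinematics, (b) source-level band
power, (c) directed coupling between motor regions, and (d) how well the
spectral changes predict the kinematic improvement. Because the patient
recordings that motivate this kind of analysis are not publicly
distributable, the package ships a synthetic-data module whose generative
models have closed-form ground truth; every downstream stage is validated
against that truth. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not establish.

## The synthetic spiral model

A drawn spiral is modelled as an Archimedean curve `r = b·θ/(2π)` traced at
angular speed `ω`, so the tangential velocity is

```
v_t(t) = r(t) · dθ/dt = (b/2π) · ω² · t .
```

Parameters of `spiral_gen_config()`, with units and defaults:

* `spacing_cm = 1.5`, `n_loops = 3` — the standard tablet template: three
  loops, 1.5 cm apart, ending at 4.5 cm radius.
* `fs_hz = 100` — tablet sampling rate.
* `base_angular_speed = 2π·3/14.3` rad/s — one full template in ≈14 s, a
  realistic drawing time for a bradykinetic patient.
* `level_speed_gain = 0.12` — fractional angular-speed increase per level
  step. Because the drawing always covers the same three loops, the mean
  tangential velocity is *linear* in level with slope/intercept equal to
  this gain, which is what the kinematic slope analysis estimates.
* `entropy_knob` — relative SD of a smooth (0.25 s correlation time)
  log-normal modulation of the angular speed. It injects velocity
  irregularity without ever reversing the drawing direction; larger values
  raise the sample entropy of the velocity series.
* `jitter_sd` (cm) — white positional noise; `tremor_amp`/`tremor_hz` — an
  optional oscillatory contaminant, off by default.

The cohort generator (`gen_cohort_spirals()`) draws per-subject random
effects once per subject: a log-normal base-speed factor (SD 0.15) and a
Gaussian speed gain truncated at zero (SD 0.04 around the template gain).
The traced task is drawn 15 % slower and 40 % more irregular than
self-paced drawing, and switching stimulation on (levels ≥ 1) shrinks the
entropy knob by 30 % — irregularity reacts to the ON state rather than to
the graded intensity, while speed improves gradually. These effect sizes
are free parameters of the generator, chosen once as a plausible clinical
regime; they are not estimates of any particular dataset.

## Kinematics

`tangential_velocity()` takes the spiral centre to be the **first recorded
sample** (the task instruction is to start at the centre; a centroid would
be biased toward the outer loops), unwraps the angle by accumulating signed
increments in (−π, π], differentiates with central differences
(second-order one-sided stencils at the boundaries, per-interval spacing
for non-uniform time stamps), and multiplies by the instantaneous radius.
The net rotation sign is normalized away so both drawing directions give
non-negative velocity. The first ~3 samples sit at the degenerate centre
where the angle is undefined; accuracy claims start beyond them. No
smoothing is applied before differentiation — the generator's noise-free
traces need none, and smoothing is a user decision for real tablet data.

Sample entropy follows the standard template-counting definition:
`SampEn(m, r) = −ln(A/B)` where `B` counts pairs of length-`m` templates
and `A` pairs of length-`m+1` templates within Chebyshev distance `r`,
self-matches excluded, both counts over the first `N−m` start points.
Defaults `m = 2`, `r = 0.2·SD` of the series. Two conventions had to be
pinned:

* the SD entering `r` is the **per-spiral** SD (not the per-condition SD
  over five spirals), so each spiral's irregularity is scored on its own
  scale;
* a constant series yields `r = 0` and all template distances equal to
  zero, hence `A = B` and `SampEn = 0` — the natural limit of the
  definition. Only `A = 0` or `B = 0` (no matching templates at all) is
  flagged undefined (`NA` with a warning), never silently ±∞; undefined
  values are dropped from five-spiral averages with a warning.

The implementation is vectorized but algebraically identical to the
exhaustive O(N²) pair count; the test suite asserts *exact* equality
against a nested-loop oracle for series up to N = 300.

Per-parameter slopes across levels are ordinary least squares on the
**ordinal level index** 0–3, not on milliamps: the levels are the
within-subject design variable, and per-patient currents differ. (Mean
currents rise non-linearly with level, so a slope on mA would mix the
design with per-patient titration.)

## The synthetic neural network

Each region of interest is a damped AR(2) resonator with complex-conjugate
poles at radius `damping` (default 0.85) and angle `2π·f0/fs`: the simplest
stationary band-limited source. The default five-region motor set
{STN, M1, SMA, DPMC, VPMC} places STN and M1 at 25 Hz (high beta) and the
premotor regions at 80 Hz (high gamma); the extended eight-region montage
adds pre-SMA and DLPFC (25 Hz) and a visual-cortex reference at 10 Hz whose
parameters never change with level.

Directed edges enter the coefficient matrices through a **band-selective
lag kernel** rather than a single lagged coefficient. A single-lag
cross-coefficient has a frequency-flat transfer `|Ā_ij(f)| = |a|`, so any
level modulation of such an edge moves the gPDC numerator in *every* band —
making it impossible to have, e.g., a level-dependent beta edge whose
high-gamma directed coherence stays flat, which is precisely the
dissociation the analysis is designed to detect. The kernel (length 16 at
fs = 500) is designed by equality-constrained least squares: unit response
with linear phase at the edge's band centre, minimal energy over the
opposing band (55–110 Hz for beta edges, 10–35 Hz for gamma edges). The
achieved out-of-band response is below 1 % of the in-band response, so an
edge's level modulation is invisible outside its own band to well below
estimation noise.

Level modulation is multiplicative: edge gain `g·(1 + slope·level)` with
slope −0.25 for the bidirectional STN–M1 beta edges (hyperdirect
suppression) and +0.5 for premotor↔M1 gamma edges (cortical facilitation);
innovation SDs shrink by 12 %/level in STN/M1 and grow by 8 %/level in the
premotor regions, giving the band-power tables their level trends. Base
gains (0.04 beta, 0.10 gamma) are bounded by stability: the bidirectional
beta loop has gain `(g/|Ā_STN(25)|)·(g/|Ā_M1(25)|)` at resonance, and with
`|Ā(f0)| ≈ 0.09` at damping 0.85 the companion spectral radius reaches
0.97 at level 0. Every construction is checked against the companion
matrix; an unstable request errors with the offending edge named.

Simulation starts from zeros and discards a burn-in of `10·p` samples.
The simulation rate (500 Hz) and per-condition lengths (2×10⁴ samples for
connectivity work, i.e. 40 s) are the package's study conditions: they keep
a 100-seed Monte Carlo affordable while leaving MVAR estimation noise an
order of magnitude below the designed level effects.

The sensor model mixes sources through a smooth random lead field
(row-smoothed Gaussian matrix, unit-norm columns — spatial spread without
anatomy), then adds white sensor noise, 50 Hz line contamination with
random per-sensor gains, and optionally a rectangular ~130 Hz pulse train
projected through a random topography. The pulse train reproduces only the
spectral signature of a stimulation artifact; it is not a biophysical
stimulation model, and ICA-style artifact decomposition is out of scope —
the preprocessing contract assumes cleaned input or synthetic data with the
artifact disabled.

## Preprocessing

Common average reference, then 4th-order Butterworth band-pass
(0.5–300 Hz defaults; the low-pass must sit below Nyquist, so pipeline
configurations at fs = 500 use 200 Hz), then biquad notches at
50/100/150 Hz with quality factor 35. All filters are applied
forward–backward (zero phase): directed-coherence estimates rest on
cross-region *lag* relations, and a causal filter's phase distortion would
corrupt exactly what the connectivity stage measures. The cost — effective
order doubling and edge transients — is documented behaviour; amplitude
assertions in the tests measure the interior of long signals.

## Source extraction

LCMV beamforming with scalar (fixed-orientation) sources, one lead-field
column per ROI: `w_s = (l_sᵀC⁻¹l_s)⁻¹ l_sᵀC⁻¹`, which passes the source
with unit gain (`w_sᵀl_s = 1`, asserted to 1e−8) while minimizing output
variance. The covariance is estimated from the recording itself with
optional diagonal loading `λ·mean(diag(C))`; λ = 0.05 by default, and an
ill-conditioned covariance aborts with advice to raise λ rather than
returning garbage filters. Unit-gain (not unit-noise-gain) normalization
keeps the output variance identity `w_sᵀCw_s = (l_sᵀC⁻¹l_s)⁻¹` exact,
at the price of the usual depth bias — irrelevant here because the lead
field is known exactly in every use the package makes of it.

## Spectra and band power

Welch PSD with 1-s Hamming windows and 50 % overlap (1 Hz resolution),
one-sided density normalization, per-segment demeaning. Band power is the
**trapezoidal integral** of the density over the band (inclusive
endpoints), not the mean density — the two differ only by the bandwidth
factor, but the integral makes the white-noise identity (total power =
variance) and the sinusoid identity (A²/2 into its band) exact test
targets. Power is absolute, not relative; slopes across levels are fitted
on raw power, with log-power available to users who want it.

## Connectivity

MVAR models are fitted by multichannel least squares on lagged regressors
with a degrees-of-freedom-corrected residual covariance; order selection
minimizes the multivariate BIC over 1..20 when requested, but the pipeline
default pins the order to the generator's kernel length (16) — with the
generating order known, scanning is spent computation. The fully
multivariate five-region model is fitted once per condition on the
concatenated recording (per-epoch fitting and averaging would estimate the
same coefficients with more variance). Generalized partial directed
coherence is evaluated on a 0.5 Hz grid over 1–100 Hz; band summaries are
arithmetic means over the grid points in the band. The column
normalization `Σ_i |π_ij(f)|² = 1` is an algebraic identity of the
definition and is asserted to 1e−10 on every computed spectrum.
Phase-randomized surrogates (per-channel phase scrambling, amplitude
spectra preserved) provide a null for directionality checks; they are a
utility, not a thresholding step in the headline pipeline, which follows
the level-wise ANOVA design instead.

## Prediction

Gaussian-kernel ε-SVR predicts each subject's velocity slope from the
eight ROI power slopes of one band (one model per band and task).
Hyperparameters are pinned explicitly rather than inherited from any
library's defaults: C = 1, γ = 1/8 on z-scored features, ε = 0.1·SD(y).
Accuracy is repeated 5-fold cross-validated R² (10 repeats), reported as
mean ± SD across repeats. Attribution is **exact** Shapley: with eight
features, all 256 coalitions are enumerated, absent features are replaced
by background means (the marginal-expectation value function of Kernel
SHAP, exact rather than regression-approximated), and efficiency
(`Σφ_i = f(x) − f(background)`) holds to machine precision. Twelve
features is the hard enumeration limit; beyond it the function refuses
rather than silently approximating.

The synthetic cohort behind the recovery experiments draws a latent
per-subject response strength `u` (standard normal truncated at ±2 —
clinical improvements saturate, and bounded support keeps held-out
predictions inside the training range of the RBF model), sets the velocity
slope to `u` plus noise (SD 0.1) and the informative ROI power slopes
(M1, DLPFC by default) to `−u` plus noise (SD 0.25), all other features
pure noise. In this regime the pinned SVR recovers a cross-validated
R² of ≈0.65–0.70 — the operating range reported for band-limited
prediction of drawing-speed improvement — and the recovery experiments in
the test suite run it across 50 cohort seeds.

## Statistics

* Paired t via `t.test`; zero-difference vectors short-circuit to
  `t = 0, p = 1` (flagged) rather than 0/0.
* Wilcoxon signed rank uses the **W⁺ convention** (sum of positive ranks),
  drops zero differences (Wilcoxon's original prescription), computes the
  exact two-sided p from the signed-rank null for n ≤ 25 without ties
  (identical to 2ⁿ sign enumeration, asserted in the tests), and otherwise
  a tie-corrected normal approximation with continuity correction.
* The repeated-measures ANOVA is the one-within-factor design: level
  tested against the subject × level interaction, `F(k−1, (k−1)(n−1))` —
  `F(3, 111)` at n = 38. It is computed through `aov` with an `Error`
  stratum; a hand sums-of-squares decomposition serves as the independent
  oracle in the tests and as the error term for the Tukey studentized-range
  post hocs (`ptukey` with the interaction df). No sphericity correction is
  applied by default; a Greenhouse–Geisser option adjusts the df when
  requested. Under an iid Gaussian null the test is exact, and a
  1000-replicate calibration check keeps the empirical size at α = 0.05
  within ±1.5 %.
* The five-way interaction ANOVAs of full clinical designs are out of
  scope: they cannot be validated without patient data and add no reusable
  computation.

## What the synthetic validation does and does not show

Passing the ground-truth round trips establishes that the estimators are
*correct*: the gPDC implementation evaluates its definition exactly, the
MVAR fit recovers generating coefficients, the beamformer inverts its own
forward model, SampEn equals the brute-force count. It does **not**
establish field validity on real recordings: the generator is stationary
(no beta bursts or movement-locked dynamics), its lead field is random
rather than anatomical (no correlated volume-conduction structure), its
artifacts are spectrally but not biophysically realistic, and the cohort
feature model is linear in a single latent response. Effect directions in
the generator are design choices that mirror the motivating physiology,
not discoveries.

## Known limitations

* Scalar sources only; no free-orientation or whole-brain beamforming.
* No EDF/BrainVision readers — plain CSV/TSV matrix formats with JSON
  sidecars are the interchange contract.
* Exact Shapley is capped at 12 features; no sampling fallback.
* `fit_mvar` warns (rather than errors) on an unstable fitted model so the
  user can inspect the data; downstream gPDC values from such fits are
  still well-defined algebraically but not interpretable as a stationary
  spectrum.
* The DBS pulse artifact is strictly periodic; real stimulators jitter.
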