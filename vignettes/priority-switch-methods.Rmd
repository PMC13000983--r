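---
title: "Models and methods behind wmswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmswitch)
```

## The scientific problem

wmswitch analyzes a two-item orientation working-memory task in which an
auditory retro-cue on every trial designates one of two memorized oriented
bars as relevant. Because the cue frequently switches between the items,
the paradigm isolates the act of re-prioritizing memory content from memory
load: both items must be retained throughout a 16-trial block. The package
implements the full analysis chain for such experiments — behavioral
psychometrics, oscillatory power analysis, multivariate decoding of the
memorized orientations, and group-level permutation statistics — together
with a synthetic-data generator that plants the hypothesized effects, so
every stage can be validated end to end without access to raw recordings.

## Task model

Blocks hold two orientations drawn from a 16-point grid (2.8125° + k·11.25°)
under the constraint that they are neither identical nor orthogonal, so the
circular "item distance" between them takes one of seven values
(11.25°…78.75°). Probes are drawn from a grid offset by 5.625°, so the
probe-minus-target offset is never 0° or 90°. After every switch the number
of cue repeats is drawn from a distribution on 1..7; we use a truncated
geometric with q = 0.38, whose mean run length (≈2.4) reproduces the
roughly 1 : 1.2 : 1.4 mix of switch, first-repeat and later-repeat trials
characteristic of this design. The first trial of each block is neither a
switch nor a repeat and is excluded from condition contrasts.

For short simulated sessions (fewer than ~32 blocks) the generator offers
`balance_orientations = TRUE`, which samples block pairs with a low-count
preference so all 16 orientations occur often enough for the decoder's
class means. Full-length (128-block) sessions use unconstrained random
pairs, where coverage is guaranteed in practice.

## Behavioral model

The probability of a "clockwise" response given the signed probe offset
θ (folded to (−90°, 90°]) is

P(cw | θ) = (1 − λ) Φ(θ; 0, σ) + λ,

with lapse rate λ, inverse precision σ (degrees) and bias fixed at 0. The
swap-extended model routes a fraction p_swap of comparisons to the uncued
item:

P(cw | θc, θu) = (1 − p_swap − λ) Φ(θc) + p_swap Φ(θu) + λ.

As printed this form is asymmetric: its asymptotes are λ at θ → −∞ and 1 at
θ → +∞, i.e. all guesses land on "clockwise". We implement this literal
form as the default and provide the standard symmetric variant
(1 − 2λ) Φ + λ behind `form = "symmetric"`, because the literature usually
intends the symmetric form but the printed equation is the asymmetric one;
both are covered by tests. A single σ is shared between the cued and swap
components.

Fitting maximizes the Bernoulli likelihood with bounded L-BFGS-B from 10
low-discrepancy starting points (λ, p_swap ∈ [0, 0.5], σ ∈ [1°, 90°]).
Bounded multi-start avoids boundary traps on small per-condition samples;
the deterministic start grid makes fits reproducible independently of the
ambient random-number state. Fits that end on a bound are flagged rather
than rejected — with degenerate data (e.g. all-clockwise responses) the
boundary fit is the honest answer and σ is unidentifiable.

For psychometric fits "repeat" pools first repeats and later repeats; the
switch-cost summary keeps the three conditions separate and uses the median
RT of correct trials.

The generator's RT model — a shifted lognormal whose median may depend on
condition and item distance — is pure plumbing for the RT analyses, not an
estimate of any real latency mechanism.

## Synthetic EEG

Epochs span −0.75 to +2.5 s around cue onset at 250 Hz across a 61-channel
extended 10-20 montage built geometrically on the unit sphere. The
background is 1/f noise (α = 1) from 24 sources mixed through a random
spatial matrix, plus white sensor noise (SD 0.5). On top of this the
generator plants:

* an orientation-tuned evoked pattern on the 17 posterior sensors, with
  channel weights cos(2(θ_cued − φ_c)) for fixed random preferred angles
  φ_c, gated by a Gaussian post-probe envelope (center 1.1 s, SD 0.15 s) —
  all orientation coding lives in a two-dimensional cos(2θ)/sin(2θ)
  subspace, which is what makes the decoded tuning curves cosine-shaped;
  a weaker uncued-item pattern uses independent preferred angles unless
  `uncued_shares_weights = TRUE`;
* a frontal 6 Hz theta oscillation whose amplitude grows by
  `theta_switch_gain` (default 0.25) on switch trials;
* a central 20 Hz beta oscillation whose amplitude falls by
  `beta_switch_gain` (default 0.12) on switch trials, falls further by
  `beta_distance_slope` (default 0.002 per degree) with item distance, and
  is jittered lognormally per trial; on switch trials the evoked amplitude
  is coupled to that jitter so their correlation approximates
  `beta_decoding_coupling` (default −0.3).

Oscillations are gated to the post-cue interval so the pre-cue baseline is
condition-free. The default amplitudes (0.7 against the unit-variance
background) were chosen once, by simulation, so that baseline-relative
log-power changes are of order 1 dB — the regime in which such effects are
reported for scalp EEG. With all gains and the evoked amplitude at zero the
output is pure noise, statistically identical across conditions; this is
the null configuration used by the calibration tests.

What the generator does **not** emulate: eye/muscle artifacts, volume
conduction from realistic dipole geometry, non-stationary behavior
(fatigue, learning), or between-participant variability in montage and
noise spectra. Passing tests therefore demonstrate that the pipeline
recovers effects it is pointed at under clean conditions — not that the
effects exist in any particular real dataset.

## Spectral analysis

The surface Laplacian uses spherical splines: potentials are interpolated
with kernels built from Legendre series (stiffness order 4, truncated at
degree 10, regularization 10⁻⁵ on the fitted coefficients) and the
Laplacian is read off the companion series, scaled by the conductivity
(0.33 S/m) and squared head radius. The estimate is reference-free and
turns focal topographies into center-surround patterns, which concentrates
the planted central beta effect.

Time-frequency power uses a Hann-tapered sliding window of five cycles per
frequency (2–40 Hz in 1 Hz steps, 40 ms time steps), normalized so a
sinusoid of amplitude A yields linear power A²/2, then converted to dB
(10·log10). Timepoints whose window extends beyond the epoch are `NA`
rather than zero-padded — edge artifacts must not leak into the −0.75 to
−0.25 s baseline. A consequence of the epoch length is that frequencies
below ~5 Hz have no valid baseline samples: baselined maps are restricted
to the rectangle of cells finite for every participant (≥5 Hz), so the
"theta" cluster analysis effectively covers 5–8 Hz. The planted theta
oscillation sits at 6 Hz and is unaffected.

Baseline correction subtracts the mean pre-cue dB level; the default is the
average across trials per channel and frequency, which is
condition-independent and therefore cannot move condition contrasts. A
trial-wise option (`per_trial = TRUE`) exists because baseline choice is a
known sensitivity in this literature.

Band-power presets follow the field's conventions: beta 15–25 Hz at nine
central-parietal channels, theta 4–8 Hz at six frontal channels, alpha
8–14 Hz at eight posterior channels, each in the 0.4–0.8 s late cue window.

## Decoding

Features pool the 17 posterior sensors over a 450 ms backward-looking
window, decimated to one sample per 12 ms (every third sample at 250 Hz;
plain decimation, since the signal is already band-limited by acquisition).
The window at 12 ms spacing contains 38 inclusive grid points; we take the
37 strictly inside (t − 450 ms, t], which reproduces the canonical
37 × 17 = 629 feature count. Features are demeaned across the window
within each sensor to limit carryover of decodable signal between windows.

Decoding is 13-fold cross-validation over contiguous block groups (12
folds of 10 blocks plus one of 8 at 128 blocks; block counts that do not
divide evenly shrink the later folds). Per fold, 16 orientation class
means and a noise covariance are estimated from the training folds; the
covariance is the Ledoit-Wolf analytic shrinkage estimate computed on
residuals after removing class means, which stays invertible with 629
features and a few hundred trials. Each test trial yields 16 Mahalanobis
distances (unsquared, by convention; a `squared` flag exists because the
cosine summary is compatible with either), circularly shifted to center on
the trial's orientation and sign-flipped into a tuning curve. The trial's
decoding score is the cosine vector mean with doubled angles,
Σⱼ cos(2θⱼ)·Dⱼ, which is zero for a flat curve, positive for tuning peaked
at the true orientation, and invariant to additive offsets. Distances are
inverted before the summation; the placement of the inversion only fixes
the sign convention.

If an orientation is absent from a fold's training portion (possible in
short sessions), its mean is pooled over all available trials of that
orientation, with a warning; an orientation absent from the entire session
is an error. Cued and uncued targets train and test on that item's
orientation; the cross target trains on cued and tests on uncued labels.

## Group statistics

Trial-level regressions z-score the outcome and every predictor within
participant (and condition); interaction columns are products of z-scored
mains, z-scored again. Group inference is a one-sample t-test on the
standardized coefficients with Cohen's d = mean/SD.

Cluster-based correction: per-cell one-sample t maps are thresholded
two-sided at p < 0.05 (the conventional cluster-forming default; the
threshold is configurable), suprathreshold cells are grouped into same-sign
4-neighborhood clusters, and each cluster's mass (sum of t) is referred to
the permutation distribution of the maximum |mass| under random
per-participant sign flips. P-values use the +1 correction, so the smallest
attainable value is 1/(n_perm + 1) — with 10,000 permutations a cluster at
the floor is reported as p < 10⁻⁴.

The one-way repeated-measures ANOVA takes its sums of squares from
`stats::aov` with a participant error stratum; Greenhouse-Geisser
correction (computed from the double-centered within-participant
covariance) is on by default, giving the fractional degrees of freedom
conventional for these analyses, and can be disabled.

The binned analysis ranks each participant's trials by band power, splits
them into eight equal-count bins (remainder trials go to the lowest bins),
and regresses the mean decoding score on bin index.

## The study runner

`run_synthetic_study()` simulates N independent participants and executes
the full chain: switch-cost and psychometric analyses; baselined
time-frequency switch-vs-repeat contrasts at central and frontal channel
sets with cluster correction; item-distance regressions on beta and theta
power plus a distance-level ANOVA (restricted to distance levels observed
for every participant, since short sessions may miss levels); decoding of
cued, uncued and cross targets with per-trial scores averaged over the
post-probe 1.0–1.2 s window; power→decoding regressions, the multiple
regression with item distance and its interaction, and the 8-bin analysis.
Per-participant seeds derive from the master seed by one `sample.int` draw
each, and the permutation stage is reseeded deterministically, so a rerun
with the same configuration and seed reproduces the output bundle byte for
byte. `run_import_study()` runs the identical chain on datasets exported by
`export_dataset()` (TSV trial tables; epochs as a `%.17g` text matrix with
a JSON sidecar, chosen so that the round trip is bit-exact).

Two profiles exist: `"full"` (43 participants × 128 blocks, 10,000
permutations, decoding 0.8–1.4 s) matches the study design; `"ci"`
(8 participants × 16 balanced blocks, 1,000 permutations, decoding
1.0–1.2 s) is the scaled-down configuration used by the test suite and the
worked examples, sized to run on a laptop in minutes. The tests' problem
sizes (3–16 participants, 13–128 blocks, 100–1,000 permutations) are the
package's own choice of scale for routine verification.

## Numerical choices and limitations

* Orientation space is 180°-periodic throughout; every tuning computation
  doubles angles. Probe offsets are folded to (−90°, 90°] before any Φ
  evaluation.
* TFR output timepoints snap to the nearest sample (< 2 ms error at
  250 Hz); analysis windows are chosen as multiples of the 40 ms step so
  the standard windows land exactly.
* The shrinkage intensity is clipped to [0, 1]; with degenerate residuals
  the estimate degrades gracefully toward the scaled identity.
* Permutation p-values never reach 0 (+1 correction) and the false-positive
  calibration is Monte-Carlo verified in the test suite.
* The generator's planted effect sizes are constructions, not measurements:
  recovering them shows internal consistency of the chain, and the
  magnitude ordering of recovered group statistics is verified to be
  monotone in the planted magnitudes.
* Raw-EEG cleaning (filtering, artifact rejection, ICA, channel
  interpolation) is out of scope: the import path expects epoched,
  preprocessed data.

```{r example, eval = FALSE}
# a scaled-down end-to-end run
cfg <- run_config(profile = "ci", n_participants = 8)
bundle <- run_synthetic_study(cfg, seed = 1, out_dir = "wmswitch-run")
tidy(bundle$cluster_central)
bundle$power_decoding_tests
```
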