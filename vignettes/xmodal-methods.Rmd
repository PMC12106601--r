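---
title: "xmodal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{xmodal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmodal)
```

`xmodal` packages the modeling and analysis pipeline for studying how a
stimulus–response rule learned in one sensory modality (touch)
generalizes to another (vision). This vignette documents the methods
behind each module.

## 1. Network model

### Dynamics

The model comprises four cortical areas — two primary sensory areas (V1,
S1) and two association areas (RL, AL) — each an excitatory/inhibitory
rate network with `N_E` excitatory and `N_E / 4` inhibitory units. Unit
activations `x` evolve by the Euler–Maruyama discretization (`dt` = 1 ms)
of

```
tau * dx/dt = -x + W r + I(t) + sigma_x * noise
r = f(x)
```

with `tau_E` = 20 ms for excitatory and `tau_I` = 10 ms for inhibitory
units, and the rectified-sigmoid transfer function

```
f(x) = beta * max(0, sigmoid((x - x0) / rho) - sigmoid(-x0 / rho))
```

so that `f(0) = 0` exactly (a quiescent network stays quiescent) and
rates saturate at slightly below `beta`.

Within every area, connectivity is all-to-all with fixed weights
`W_EE`, `W_EI`, `W_IE`, `W_II` (E→E, I→E, E→I, I→I). Feedforward
projections from each primary area target both excitatory and inhibitory
units of both association areas with weight `3.2 * W_EE`; feedback
projections from the association areas target excitatory units only,
with weight `0.4 * W_EE` to the matching primary area and `0.04 * W_EE`
otherwise. `build_connectome()` assembles the weight matrix;
`connectome_blocks()` exposes its block structure.

### Trial structure and decision

Each trial consists of a 200 ms inter-stimulus interval followed by a
200 ms stimulus: a constant input `c_s` to the excitatory units of the
stimulated primary area representing either the "top" or "bottom"
stimulus position. State is reset between trials.

Two readout units (Go and No-go) integrate area activity through plastic
weights `W_z` (initialized at mean 0.5, SD 0.1, clipped to `[0, W_max]`).
Each readout drives a drift–diffusion decision variable

```
d(delta) = z dt + sigma dW
```

and the first readout whose `delta` reaches the threshold `theta0`
determines the action (Go or No-go); if neither crosses during the
stimulus, the trial is a no-response.

### Reward-modulated Hebbian plasticity

After each decision, a scalar reward signal `c_r` is formed from the
chosen readout's activity excursion, positive for correct and negative
for incorrect responses. Weights onto the readouts update by the
Hebbian rule

```
dW_z = gamma * dt * z_tilde * r
```

accumulated over the trial, clipped to `[0, W_max]`, and each
readout-by-area weight block is then renormalized to mean 0.5 by a
water-filling procedure (`renormalize_block()`) that respects the
`[0, W_max]` bounds exactly.

### Silencing

`silenced = "RL"` or `"AL"` removes the corresponding association area
from the dynamics; silencing RL additionally freezes its readout weight
block and raises the Hebbian normalization constant from
`alpha = 1 / (6 N_E)` to `1 / (2 N_E)`, reflecting the loss of a
learning pathway.

### Experiments

`experiment_config()` + `run_experiment()` simulate a full task-switch
experiment: `n_pre` trials driven through S1, then `n_post` trials
through V1, with the position rule preserved or reversed at the switch,
over `n_runs` independently seeded runs (run `k` uses `seed + k - 1`).
`model_performance()` computes sliding-window accuracy (from trial
outcomes, or from the readout sign with `mode = "readout"`),
`time_to_criterion()` the first window reaching the criterion, and
`glance()` a per-run summary.

```{r network-demo}
cfg <- experiment_config(switch = "preserve", silence = "none",
                         n_pre = 40, n_post = 40, n_runs = 2,
                         window = 15, criterion = 0.75, seed = 1)
ex <- run_experiment(cfg, model_params())
glance(ex)
```

The per-step dynamics (including the plasticity accumulation) are
implemented in C++ for speed; a pure-R reference path exists and the two
are verified equivalent in the test suite.

## 2. Behavior metrics

Session logs are tibbles with a `type` column (`"go"`, `"no-go"`,
`"catch"`) and a logical `lick` column.

* `conditional_lick_probability()` — per-trial lick probability
  conditioned on trial type, over a trailing (default) or centered
  window. Windows containing no trial of a class yield `NA`, never 0.
* `discrimination_performance()` — `(Hit + (1 - FA)) / 2`, from Go hits
  and No-go false alarms.
* `detection_performance()` — treats catch trials as the "absent"
  class: the better of `avg(Hit, CatchCR)` and `avg(FA, CatchCR)`, so
  a mouse licking to any stimulus still scores detection.
* `session_end_index()` — the session is considered over at the first
  trial after the peak of the Go lick curve where it drops strictly
  below 66% of its maximum.
* `switch_aligned_average()` — aligns per-mouse session series on the
  switch session and averages (mean, SEM, n).
* `learning_rate()` — the linear-regression slope over exactly three
  consecutive session performances.

```{r behavior-demo}
log <- gen_session(lick_policy(0.9, 0.2, 0.1), n_trials = 200, seed = 1)
discrimination_performance(log)
detection_performance(log)
```

## 3. Imaging analysis

### The sparse-noise condition grid

`stimulus_grid()` enumerates the 54 conditions of the visuo-tactile
sparse-noise protocol: 3 whisker states (B2, C2, none) x 9 visual
positions (8 + blank) x 2 visuo-tactile delays, partitioned into blank,
visual, tactile, and multisensory conditions. Trial tensors
(`trial_tensor()`) are `neurons x conditions x trials x time` arrays of
baseline-z-scored responses with a time axis attribute.

### Responsivity and functional classes

`response_surprise()` computes, per neuron, condition, and time bin, the
surprise `-log10(p)` of a one-sample z-test of the across-trial mean
against zero (valid because traces are baseline-z-scored), evaluated in
log space so that very strong responses remain finite, together with the
across-trial coefficient of variation. `classify_cells()` applies the
inclusion rule — surprise at or above the strict threshold with CV below
threshold in at least 4 consecutive post-stimulus bins for the strict
gate, one bin at the lenient threshold for the lenient gate — and labels
neurons as visual, tactile, visuo-tactile, gated (responsive to joint
stimulation only), or unresponsive.

### The max model and the modulation index

`predict_max_model()` predicts the multisensory response of a neuron as
the bin-wise, trial-wise maximum of its two unisensory constituent
responses. The multisensory modulation index compares measured and
predicted means:

```
MI = (measured - predicted) / (|measured| + |predicted| + epsilon)
```

positive for enhancement, negative for suppression.
`mi_significance()` tests MI against zero per bin with a bootstrap-t
procedure (outer resamplings studentized by inner-resampling standard
errors; default 2000 x 25). `mi_range()` integrates the MI trace over
the response window for every *valid* multisensory condition — one with
a responsive unisensory constituent and significant modulation in at
least one bin — and reports the min–max range of these integrals. Note
that the trial-wise maximum of noisy traces is an upward-biased
predictor, so even perfectly max-consistent neurons sit at slightly
negative MI; the index is therefore interpreted relatively.

### Tuning

`position_preference_index()` maps the rectified center of mass of the
8-position (or 2-whisker) response profile to `[-1, 1]`.
`tuning_selectivity()` fits a four-parameter Gaussian to the visual
profile (Levenberg–Marquardt, `fit_gaussian_profile()`) and reports
`min(1, sigma_ref / sigma)` with `sigma_ref` the sigma of a
one-position-wide (FWHM = 1) Gaussian. `cluster_streams()` splits
visuo-tactile neurons into two processing streams by k-means on map
coordinates, labeled by anchor proximity.

### Population decoding

`train_bayes_decoder()` fits a Poisson-form naive-Bayes decoder: per
neuron and class, the mean training response (floored at `epsilon`
before the log). Decoding computes, per trial,

```
ll(class) = sum_j f_j * log(t_j(class)) - sum_j t_j(class)
```

and takes the argmax, breaking exact ties uniformly at random.
`decoder_features()` extracts per-neuron features at the neuron's most
responsive position within each category, pooling the two delay labels.
`crossmodal_accuracy()` runs the full procedure: for each neuron-pool
resampling, trials are reordered within class per neuron (removing noise
correlations), features are min–max normalized with constants from the
training folds only, and the decoder is evaluated both on held-out
trials of the training modality (fourfold cross-validation) and on all
trials of the other modality. A `shuffle_labels` switch provides the
chance-level control.

## 4. Wide-field maps

### Preprocessing

`pixel_movie()` bundles a `ny x nx x frames` movie with a trial/epoch
table and the condition grid. `preprocess_movie()` applies, per pixel, a
second-order Butterworth band-stop filter (default 9–15 Hz, forward and
backward for zero phase) to remove heartbeat artifacts, then a
Daubechies-4 discrete-wavelet detrend (`dwt_detrend()`: 6-level
decomposition, approximation coefficients zeroed, signal reconstructed)
to remove slow drift.

### z-scoring and trial rejection

`zscore_and_reject()` z-scores each trial against per-pixel statistics
of the blank trials, in two passes: blank trials whose absolute baseline
mean exceeds the threshold (default 0.5 SD) are rejected, reference
statistics are recomputed from the survivors, and all trials are then
z-scored and subjected to the same baseline test. Trial baselines are
exactly zero after the subtraction.

### Maps

* `condition_response_map()` — per-pixel median across trials, then mean
  across the requested conditions, in a response window given in
  seconds.
* `vertical_position_map()` — upper-field minus lower-field responses
  (visual: positions 7–8 vs 3–4 including multimodal conditions;
  tactile: whisker B2 vs C2), each side normalized to `[0, 1]` before
  the difference so the map is bounded in `[-1, 1]`.
* `modality_preference_map()` / `multisensory_enhancement_map()` —
  normalized differences of the maximum visual vs tactile response, and
  of the multisensory response vs its unisensory maximum. Because of
  the normalization these maps show *spatial* deviations only; a
  globally uniform gain is removed by construction.
* `spatial_coherence_map()` — convolutionally (8 x 8 patches, stride 1)
  the Pearson correlation of matching patches of two maps, scaled by the
  average peak-to-peak range of the two patches so that unresponsive
  regions contribute little. Identical maps give positive values,
  sign-flipped maps the exact negation, independent maps values near 0.
* `map_gradient()` / `gradient_angle_mismatch()` — coarse-scale finite
  differences (default scale 4 pixels) after Gaussian smoothing; the
  mismatch statistic is the mean absolute angular difference between two
  maps' gradient fields in degrees.
* `map_orientation()` — the dominant axial orientation of a map's
  gradient field: the magnitude-weighted circular mean of the doubled
  gradient angles, computed over the interior (a border of
  `scale + ceiling(smooth_sigma)` pixels is trimmed, where edge-clamped
  differences are biased), returned in `[0, 180)` degrees.

## 5. Synthetic data

All generators are seeded and attach their ground truth as an attribute.

* `lick_policy()` + `gen_session()` — Go/No-go logs with per-type lick
  probabilities, trial proportions 0.3/0.5/0.2 (go/no-go/catch), and an
  optional exponential disengagement decay after a breakpoint.
* `neuron_spec()` + `gen_trial_tensor()` — 54-condition trial tensors.
  Visual tuning is Gaussian over the 8 positions; tactile responses are
  whisker-specific with a 0.1 cross-whisker factor; delayed conditions
  shift the tactile response by 0.15 s; multisensory modes scale the
  max-model trace (`enhanced` / `suppressed`) or leave it
  max-consistent; `gated` neurons respond to joint stimulation only.
  Baseline bins carry pure unit-variance noise, so generated tensors are
  z-scored by construction.
* `map_spec()` + `gen_widefield_movie()` — wide-field movies with
  Gaussian response bumps whose centers move along linear topographic
  gradients (visual gradient at `grad_angle` degrees, tactile offset by
  `offset_deg`), blank conditions, optional slow drift and a 12 Hz
  artifact, and randomly interleaved condition order as in a real
  recording session.

## 6. Reproducibility

Every stochastic function takes or consumes an explicit seed; repeated
runs are bit-identical. The test suite includes oracle comparisons
(noiseless fixed points, brute-force naive Bayes, confusion-count
metrics), property tests, and an acceptance suite with explicit
tolerances; `scripts/acceptance.R` reproduces the headline
cross-modal-transfer statistic from a single seed.
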