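---
title: "Methods: gait-cycle GAF imaging and TICA-pooled tiled convolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-cycle GAF imaging and TICA-pooled tiled convolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gaitica` classifies which impairing substance — alcohol or marijuana — a
walking person has consumed, from smartphone accelerometer data alone. This
vignette documents the model, its assumptions, the tunable parameters, the
synthetic data generator, and the design decisions that were genuinely open,
in enough detail that a maintainer can judge every numeric choice. It states
no empirical result that the test suite does not itself compute.

## 1. Signal model and preprocessing

A recording is a triaxial accelerometer bout `(ax, ay, az)` at sampling rate
`fs` (default 50 Hz, a typical smartphone IMU rate). The chain is:

1. **Low-pass filter.** Human gait energy lies below ~10 Hz, so each axis is
   filtered with a 4th-order Butterworth low-pass at 10 Hz applied
   *zero-phase* (forward and backward), which squares the magnitude response
   to `1/(1 + (f/fc)^(2·order))` and cancels the phase so salient-point
   locations do not shift. No IIR design package is available in the target
   environment, so the filter is designed from scratch: bilinear transform
   of the analog prototype into unit-DC biquad sections, odd-reflection
   padding of 24·order samples against edge transients. The implementation
   was checked against an independent reference (`scipy.signal.filtfilt`)
   during development to ~1e-8 away from the edges. Note the attenuation of
   the *digital* filter at 2× cutoff is ~0.0015, stronger than the analog
   closed form 1/(1+2^8) ≈ 0.0039, because the bilinear transform warps
   frequencies upward; tests assert the bound (< 0.01), not the analog
   value.
2. **Hampel outlier filter** (window 11 samples, 3σ): a sample deviating
   from its centered rolling median by more than `3 · 1.4826 · MAD` is
   replaced by that median. Replacement (rather than deletion) preserves
   uniform sampling. Samples within half a window of either edge have no
   centered window and pass through untouched — a one-sided window flags
   legitimate edge slopes (we measured exactly this failure before adopting
   the convention). A constant window has MAD 0 *and* deviation 0; since
   the rule is "deviation strictly greater than threshold", constant
   stretches are never modified.
3. **Signal vector magnitude** `SVM¹ = √(ax² + ay² + az²)` — the
   orientation-robust scalar gait profile. (The root-sum-of-squares reading
   was chosen over a literal "square root of the sum", which is undefined
   for negative sums.)
4. **Salient points**: strict interior local minima of SVM¹. When two
   minima fall closer than `round(min_cycle_s · fs)` samples, the deeper
   one wins, ties broken toward the earlier index — a deterministic greedy
   rule verified in tests against an exhaustive oracle.
5. **Cycle candidates**: consecutive salient-point pairs, half-open
   `[start, end)` in 1-based sample indices, gated to durations in
   `[min_cycle_s, max_cycle_s]` (defaults 0.5–2.0 s; the pipeline
   configuration uses 0.9–2.0 s so that whole strides, not single steps,
   survive the gate).
6. **NCC validation**: the per-recording template is the SVM¹ profile of
   the median-duration candidate, resampled to `resample_len`; every
   candidate is scored by the Pearson-type normalized cross-correlation and
   kept if `ncc ≥ 0.6`. NCC is invariant under positive affine maps, so
   per-subject gain differences do not affect validation.
7. **Resampling**: each surviving cycle's three axes are linearly
   interpolated onto `resample_len` points (endpoints preserved), giving
   the fixed-length window the encoder needs. `resample_len` defaults to
   500 (full smartphone-scale images); the test and benchmark configuration
   uses 64 for desk-scale runtime.

The duration gate, NCC threshold, and Hampel parameters have no canonical
values in the gait-segmentation literature; all are exposed in
`segmentation_config()`.

A note on an advertised invariant: "applying the filter+Hampel chain twice
equals applying it once" cannot hold to 1e-9 for any non-ideal filter — a
second pass re-attenuates in-band harmonics and re-excites filtfilt edge
transients. Measured on clean synthetic bouts the discrepancy is ≤ ~1.5e-3,
dominated by the edges; the property test asserts 5e-3.

## 2. Gramian Angular Summation Field encoding

Each axis of a cycle window is min–max rescaled to `[-1, 1]`
(`x̃ = 2(x−min)/(max−min) − 1`), mapped to angles `φᵢ = arccos(x̃ᵢ)`, and
imaged as `Gᵢⱼ = cos(φᵢ + φⱼ) = x̃ᵢx̃ⱼ − √(1−x̃ᵢ²)√(1−x̃ⱼ²)`. The algebraic
form is used (exactly symmetric, diagonal `2x̃ᵢ²−1`); tests verify agreement
with the trigonometric form to 1e-10. Three axes give an
`n × n × 3` tensor with all entries in `[-1, 1]`.

Open choices and how they were fixed:

* **GASF vs GADF**: the summation field is the default (the common choice
  in the wearable-sensing literature this architecture comes from); the
  difference field is available via `method = "gadf"`.
* **Normalization scope**: per-cycle, per-axis min–max. This makes every
  image self-normalized and removes per-subject gain — at the price of
  discarding absolute amplitude. Class information must therefore live in
  *waveform shape*, which drives the synthetic generator design below.
* **PAA**: optional piecewise-aggregate averaging (`paa_len`) shortens the
  series before encoding so long cycles can feed small images.
* PNG export quantizes to 8 bits for inspection only; the learning pipeline
  always consumes the float tensors.

## 3. Tiled convolution and TICA pooling

**Tiled convolution.** The first layer has `n_maps = 3` feature maps with
receptive fields of side `rf_s = 8` and tile distance `tile_k = 2`: output
units whose grid offsets are congruent modulo `k` share one filter; adjacent
units are untied. The free parameters are the *banks*, an array
`[maps × k × k × (s·s·C)]`, independent of image size — filters pretrained
on 16×16 patches initialize convolution over 64×64 images. There is no bias
term. With `k = 1` the layer is a plain convolution (tested against a
brute-force oracle); with the receptive field covering the input it
degenerates to a dense projection.

**Pooling.** The second layer is the topographic ICA activation
`pᵢ = √(ε + Σₖ Vᵢₖ zₖ²)` where `z` are the simple-unit responses and `V` is
a fixed 0/1 matrix: one pooled unit per simple unit, summing the squared
responses of its 3×3 (wrap-around) spatial neighborhood *within the same
map*; on 1-D grids it degenerates to 3 neighbors. Descriptions of `V` vary
across the TICA-pooling literature; it is implemented here as a fixed
topographic pooling matrix, never updated by learning. `ε = 1e-8` smooths the square root
everywhere (objective, gradient, and supervised backprop) so the gradient
exists at `z = 0`; the original formulation has no ε.

**Unsupervised pretraining.** The TICA objective
`f(W) = Σₜ Σᵢ pᵢ(x⁽ᵗ⁾; W, V)` is minimized over sober-class GAF patches by
a projected line search: at each outer iteration compute `f` and the exact
gradient `g = ∂f/∂W` (verified against central finite differences at
relative 1e-5), propose `W − αg` with `α` starting at 1, apply the three
structural projections in order — `localize` (zero outside each receptive
field), `tie_weights` (average each tying class), then
`orthogonalize_local_RF` — and halve `α` until `f` strictly decreases.
A failed line search (30 halvings) is treated as convergence, otherwise the
loop stops on relative decrease below `tol` or at `max_outer`.

Two scope decisions deserve emphasis:

* **Orthogonalization scope.** The global form of the constraint,
  `WWᵀ = I`, is infeasible for tied, localized weights. We use
  symmetric (Löwdin) orthonormalization `W_g ← (W_g W_gᵀ)^{-1/2} W_g` within
  each *local receptive-field group* — the `n_maps` filters that share one
  receptive field. Because every grid position within a tying class sees
  the same group matrix, the transform is identical across the class, so
  the final orthogonalization preserves tying *exactly* (the tolerated
  violation is 0, not just ≤ 1e-6). Locality and tying are structural in
  the bank parametrization, so all three constraints hold after every
  accepted step; tests assert this at every step.
* **Gradient through tying.** The true gradient with respect to a shared
  bank is the *sum* over tied copies (what `tica_gradient()` returns and
  what the finite-difference check validates). The literal projection composition
  `tie_weights(localize(W − αg))` instead applies
  the *mean* over tied copies; the two differ by a per-class positive
  scale, i.e. they are the same descent directions per class. Pretraining
  uses the literal composition (`reduce = "mean"`).

**What pretraining actually does here — a caution.** The objective is
*minimized* under per-group orthonormality, with strongly undercomplete
filters (12 banks in a 192-dimensional patch space) and *unwhitened* data.
In that regime the minimizer is pulled toward low-variance directions of
the patch distribution; we measured pretrained-filter response standard
deviations ~3× below those of random orthonormal filters on the same
patches. In classical TICA the data are whitened first, which fixes the
response scale and makes the objective measure sparsity instead of
variance; the line-search algorithm implemented here has no whitening step
and the package keeps that form (a ZCA-whitened prototype did not improve downstream
accuracy either). Consequence: on the highly separable synthetic benchmark,
pretraining does not beat random orthonormal initialization — see §6.

## 4. Supervised classifier

Pooled activations are standardized by statistics frozen from the initial
training forward pass, then flattened into a single dense softmax layer
over the class order `(alcohol, marijuana)`. Training is plain mini-batch
gradient descent on the cross-entropy (defaults: lr 0.01, batch 16, 100
epochs; the benchmark uses lr 0.05, 60–80 epochs), with exact backprop
through the pooling square root and the tiled convolution (tied copies sum
into their bank). Two stabilizations were required and are deliberate
design choices, exposed as parameters:

* **Frozen feature standardization** (`feat_mu`, `feat_sd`): pooled
  energies have arbitrary scale; without standardization the head needs a
  tiny learning rate to avoid divergence.
* **Backbone learning-rate scale** (`feature_lr_scale = 0.01`): bank
  gradients are roughly an order of magnitude larger than the bank scale;
  fine-tuning at the head rate destroys the filters (we observed divergence
  to overflow within one epoch). Scaling the backbone rate down is the
  standard transfer-learning remedy. `freeze_features = TRUE` trains the
  head only.

The supervised stage does not re-impose orthonormality (the constraint
regularizes pretraining only); tying and locality are structural and cannot
be violated.

Evaluation reports cycle-level accuracy, binary F1 with **marijuana as the
positive class** (the minority class in realistic cohorts), macro F1 to
remove the convention ambiguity, ROC AUC computed as the Mann–Whitney rank
statistic with 0.5 credit for ties, and the 2×2 confusion table. Splits are
**subject-wise** by default (no subject contributes to both partitions);
a record-wise stratified mode exists because evaluation protocols vary
across studies in this area.

## 5. Synthetic gait generator

The generator is a *stated world*, not a tuning dial: it exists so the
pipeline is testable without clinical data, and its parameters were fixed
from first principles before any benchmark was scored.

Each axis is a sum of 3 harmonics of the stride frequency with
axis-specific phases and base amplitudes (ML 0.4, vertical 1.0, AP 0.6
m/s²; harmonic weights 0.5/1.0/0.25, making the step frequency dominant in
SVM¹, as in real gait). Gravity offsets the vertical axis. Phase advances
π per step; step durations are lognormal with coefficient of variation
`stride_time_cv`. Medio-lateral sway is a *stride-locked quadrature*
component of amplitude `sway_amp` added to the ML fundamental. Per-subject
random effects (lognormal gain, sd 0.1; Gaussian cadence offset, sd
0.05 Hz) are drawn once per subject so subject-wise splits are meaningful.
Gaussian sensor noise (sd 0.3 m/s²) is added per channel; gyroscope
channels are phase-shifted copies with independent noise and are not used
by the default pipeline.

Class presets (sober 1.9 steps/s, cv 0.03, sway 0.3; alcohol 1.6, 0.05,
1.4; marijuana 1.8, 0.14, 0.4) encode the qualitative directions
"alcohol ↑ sway ↓ cadence, marijuana ↑ stride-time variability". Two
modeling choices depart from naive readings and are deliberate:

* **Step-level (not stride-level) duration jitter.** Per-cycle resampling
  erases overall cycle duration, so stride-level jitter would be invisible
  in the images. Jittering each *step* makes high `stride_time_cv` appear
  as left/right asymmetry within a duration-normalized cycle — information
  that survives encoding. A gait cycle is two steps.
* **Cycle-locked sway.** An independent ~0.3 Hz sway oscillation would make
  even the noise-free, jitter-free signal aperiodic over one cycle;
  modeling sway as a quadrature component at the stride fundamental keeps
  the deterministic signal exactly periodic (a tested property) while still
  reshaping the ML channel with `sway_amp`.

What the generator does **not** emulate: biomechanically realistic
dynamics, dose–response (BAC/THC level), sensor orientation changes,
free-living bout detection, or any claim about real pharmacological gait
signatures — there is no quantitative published description of how the two
substances differ in the sensor domain. A green end-to-end test therefore
establishes that *the pipeline can learn class-discriminative cycle-shape
structure without leaking identity or labels* — not that these presets
match real impaired gait.

With the 3-harmonic waveform, SVM¹ has one dominant minimum per stride, so
detected cycles are strides and a noise-free bout yields
`floor(duration · step_rate/2) − 1` cycles (tested exactly).

## 6. Benchmarks, the ablation, and the null control

All end-to-end checks run the full chain (simulate → preprocess → encode →
[pretrain] → train → evaluate) at 64×64 images, subject-wise 70/30 splits,
seeds fixed at 1..N before scoring:

* **Benchmark** (30 impaired + 20 sober subjects, 12 s bouts, 3 seeds):
  median test accuracy ≥ 0.90, median AUC ≥ 0.95, train–test accuracy gap
  < 10 points. Bout lengths were scaled down from the 30 s generator
  default purely for test runtime; subject counts are as specified.
* **Pretraining ablation** (12 alcohol : 4 marijuana subjects, 10 s bouts,
  5 seeds): asserts median accuracy with TICA pretraining ≥ without. This
  test is an **expected failure** and is intentionally left red: both arms
  sit at the accuracy ceiling on this synthetic world (the observed median
  difference is one misclassified cycle), so an initialization advantage
  has no room to appear — and §3's analysis explains why the literal
  pretraining algorithm cannot produce features better than random
  orthonormal ones on an easy task. The directional claim it mirrors lives
  in a genuinely data-starved clinical regime that the generator does not
  (and is not asked to) reproduce. We report the honest outcome rather than
  weaken the assertion or tune the world until it passes.
* **Null-information control** (identical generator presets for both
  labels, 20+20 subjects, 8 s bouts, 5 seeds): median AUC within
  0.5 ± 0.1, guarding against any label or identity leakage through the
  pipeline. The cohort is larger than the other benchmarks because AUC
  under the null concentrates only with enough *test subjects*: at 8+8
  subjects a single-seed null AUC has standard deviation ~0.13 (measured),
  making the band a coin flip; at 20+20 it is ~0.06.

## 7. Numerical choices, degenerate inputs, limitations

* Löwdin orthonormalization rejects rank-deficient receptive-field groups
  (eigenvalue < 1e-12 relative) with a diagnostic naming the group.
* `gasf_encode` clamps inputs within 1e-12 of ±1 and rejects anything
  further out; constant cycle axes are skipped with a warning during batch
  encoding rather than aborting the batch.
* NCC is undefined for constant sequences (zero norm) and errors
  explicitly; validation treats such candidates as failures.
* Determinism: every stochastic step (generator, subject effects, splits,
  init, batch shuffling, patch sampling) derives its seed from one global
  seed via a fixed 31-bit map; identical configuration and seed reproduce
  reports bitwise. All RNG use is scoped with `withr::with_seed`, leaving
  the caller's RNG state untouched.
* Artifacts are written as CSV (sensor data, cycle reports), RDS (cycles,
  GAF tensors, weights, models), and JSON (configs, evaluation reports).
  The environment provides no R HDF5 binding; RDS stands in for the
  originally envisaged HDF5 containers.
* Known limitations: single tiled layer only (no stacking, no multi-head
  variant); plain gradient descent (no momentum/Adam); accelerometer-only
  default; cycle-level metrics treat cycles from one subject as exchangeable
  within a partition; the pretraining caveat of §3.
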