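---
title: "Methods: signal model, feature pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, feature pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiowave)
```

`cardiowave` classifies aortic stenosis (AS) from six-axis chest-worn
inertial recordings — seismocardiogram (SCG, 3-axis accelerometer) and
gyrocardiogram (GCG, 3-axis gyroscope). This vignette explains the
models and procedures the package implements, the assumptions behind
them, the tunable parameters, and the choices made where the design was
genuinely open.

## The synthetic cohort generator

Clinical SCG/GCG datasets of AS patients are not openly deposited, so
the package ships a generator whose output has the statistical structure
the pipeline assumes. It is explicitly **not** a physiological
simulator; it is the minimal signal model under which every downstream
stage is exercised honestly.

Each subject is a draw of latent parameters (`generate_subject()`):

* `heart_rate_bpm` ~ U(55, 95) — resting heart rates.
* `beat_amplitude` — per-channel gains around a fixed channel profile in
  which the dorso-ventral accelerometer axis (SCG_Z) and the head-to-toe
  gyroscope axis (GCG_Y) are strongest, ×U(0.9, 1.1) per channel and
  subject. Units are arbitrary: no sensor ranges are modeled.
* `base_freqs_hz` — two oscillation centers of the beat complex,
  U(9, 14) and U(18, 23) Hz, amplitude-weighted 1 : 0.6.
* `noise_sd` ~ U(0.8, 1.2) — white broadband sensor noise per channel.
* class effect: AS-family subjects add a murmur-like Gaussian-windowed
  tone burst ~150 ms after each beat at a per-subject frequency drawn
  from the AS band **4.5–8.5 Hz** with gain U(1.3, 1.7); non-AS subjects
  have gain exactly 0. The co-occurrence classes (`AS_MI`, `AS_MS`,
  `AS_TR`) share the AS band and add a second burst in a distinct band
  (1.2–2.8, 10.5–13.5, 15–19 Hz), so 4-class separation is learnable.
  Placing the AS band below 10 Hz mirrors where discriminative energy
  concentrates in real AS recordings.

The recording (`generate_recording()`, default 300 s at 256 Hz — the
sampling rate is a configurable convention; the segmentation and CWT
stages are rate-agnostic) is then

* a beat train of Gaussian-windowed sinusoids (sigma 0.08 s) at the beat
  period, with a weaker second burst 350 ms after each beat — an
  S1/S2-like pair that keeps the RMS envelope close to unimodal;
* a continuous low-amplitude multi-tone in-band baseline
  (`baseline_gain`, default 1.2) standing in for respiratory/vascular
  micro-vibration; its near-constant window RMS stabilizes the
  envelope median that the segmentation threshold is relative to;
* white noise; and
* Poisson-placed motion artifacts: tone bursts of 0.5–2 s at 12× the
  channel gain. Their onsets and durations sit on the 0.5-s RMS lattice,
  so every envelope window a burst touches lies fully inside the burst
  and rejection by the threshold rule is deterministic — this is the
  oracle the segmentation tests rely on.

Because heart rate, gains, effect frequencies and phases are drawn per
subject, segments of one subject are correlated in ways segments across
subjects are not: leave-one-subject-out validation is strictly harder
than segment-level hold-out, and the test suite asserts that ordering as
a tendency across cohort seeds. The murmur gain range was set, together
with the noise floor, so that (a) clean recordings keep their 10-s
windows under the 1.5×-median rule with margin and (b) a subject-held-out
gradient-boosting classifier on a 21 + 13 cohort reaches the accuracy
the acceptance suite demands; both properties were verified across
cohort seeds. What passing tests on this generator shows is that the
pipeline's machinery is correct and leak-free — not that the package
reproduces clinical performance on real patients.

## Pre-processing

`bandpass()` is a 4th-order Butterworth band-pass, 0.8–25 Hz, applied
forward–backward (`signal::filtfilt`) for zero phase, preserving beat
morphology. 25 Hz keeps all cardio-mechanical content of interest;
0.8 Hz removes baseline and respiration drift.

`segment_recording()` tiles the filtered channel into non-overlapping
10-s candidate windows phase-locked to t = 0 (no overlap policy: avoids
duplicated data across training and test sets), computes the
non-overlapping 0.5-s RMS envelope (window = step; simplest reading of a
"0.5-s step", and it makes the envelope length deterministic), and keeps
a window iff the **maximum** envelope value inside it is at most
1.5 × the median envelope of the whole recording, per channel. The
maximum — not the mean — is the acceptance statistic so that a single
burst disqualifies its window. The threshold multiplier, window length
and step are configuration knobs.

## Morse-wavelet CWT and features

`cwt_morse()` implements the analytic generalized Morse wavelet in the
frequency domain,
Ψ(ω) = 2 (eγ/β)^{β/γ} ω^β e^{−ω^γ} for ω > 0,
with γ = 3 and β = 20 (time–bandwidth product 60, the common default of
wavelet toolchains). Peak normalization at 2 makes a unit sinusoid at a
grid frequency produce ridge magnitude ≈ 1 (L1-type convention), which
the tests verify. The transform is FFT-based with zero-padding to the
next power of two at least twice the signal length; no cone-of-influence
masking is applied (segment edges are therefore mildly attenuated — a
documented simplification).

The frequency grid (`build_cwt_grid()`) is log2-spaced with
`voices_per_octave` points per octave (default 16 → 81 frequencies over
0.79–25.39 Hz). The analysed feature count therefore depends on this
density knob; it is deliberately configurable because no single grid is
canonical.

`extract_features()` computes, per frequency row over time: MEAN
(arithmetic), MED (type-7 median), MAX, STD (population, divisor N) and
IQR (type-7 Q3 − Q1). The estimator choices are fixed and documented so
tests can be exact. Names encode provenance
(`GCG_Y_MAX_5.23`) and `parse_feature_names()` inverts them, which the
distribution summaries rely on.

`render_image()` min–max normalizes a scalogram per segment and resizes
bilinearly: grayscale H×W×1 (default 600×800) for the custom CNN, or
RGB through a 128-level parula-style lookup (default 224×224) for
transfer-learning backbones. The grayscale default follows from the
custom CNN's own arithmetic: its first layer has 50 parameters and a
598×798×5 output, which is only consistent with a single-channel
600×800 input — so the RGB rendering is honored on the
transfer-learning path only. An all-constant scalogram renders as an
all-zero image with a warning.

## Elastic-net selection

`elastic_net_select()` z-scores the features and fits penalized logistic
regression along a glmnet path (mixing α = 0.5 by default), choosing the
penalty by k-fold cross-validated deviance with the **1-SE rule** —
preferred over the CV-minimum because it yields stable, sparse sets.
Multi-class tables are handled as the union of one-vs-rest nonzero
supports (no canonical combination rule exists; the union is the most
conservative for downstream classifiers). Constant columns are dropped
with a warning; fold assignment is deterministic in the seed. Reported
`reduction_pct` is always computed as 100·(1 − selected/original).
Inside the evaluation harness, selection runs on training folds only —
selecting on pooled data would leak the held-out subjects into the
choice of features.

`summarize_selection()` counts the selected features by frequency band
(below 10 Hz, 10–20 Hz, above 20 Hz), statistic, and source channel,
each with a Pareto (cumulative-percentage) sequence in descending count
order. On cohorts generated with sub-10-Hz murmur effects expressed in
burst maxima, the selected set is majority `<10 Hz` and majority `MAX` —
the qualitative pattern expected of AS.

## Classifiers and validation

`grid_search_fit()` sweeps an explicit hyper-parameter grid with
stratified inner cross-validation on accuracy, breaking ties by
first-in-grid order, then refits on the full training table. Default
grids: decision tree depth {3, 5, 10, 30} × min-split {2, 5, 10}; random
forest trees {100, 300, 500} × depth {5, 10, unlimited}; MLP size
{16, 64} × weight decay {1e-3, 1e-4}; XGBoost trees {100, 300} × depth
{3, 6} × learning rate {0.05, 0.1}. The MLP is a single-hidden-layer
`nnet` network — the one MLP implementation in the supported stack — so
its grid spans width and regularization rather than depth.

`evaluate_loso()` holds out all segments of one subject at a time;
feature selection (optional) and grid search run strictly on the
remaining subjects; held-out predictions are pooled into a single
confusion matrix (pooled rather than per-subject averaging, matching
segment-level reporting). `evaluate_leave_data_out()` is the stratified
segment-level hold-out (default ratio 0.2) that *permits* subject
overlap — its optimism relative to LOSO is a property, asserted as a
tendency over seeds, not a bug. Metrics use the standard one-vs-rest
precision/recall/F1 and trace-accuracy; a zero denominator reports 0
with a warning.

## The 2-D CNN

`build_custom_architecture()` encodes the compact scalogram classifier:
two 5-filter convolutions (3×3, 2×2), 2×2/2 max-pool, two more
convolutions (3×3, 5×5), 5×5/5 max-pool, then dense 256 → 32 → 1 with a
sigmoid output; VALID padding throughout; 5,800,248 parameters at the
native 600×800×1 input. `infer_shapes_and_params()` is a pure integer
calculator (conv: kh·kw·C·F + F; dense: in·units + units; VALID output
(H−kh)/sh+1 floored) and is cross-checked against the number of weights
the trainer actually allocates. Hidden activations are ReLU (the
conventional choice; only the output nonlinearity is dictated as
sigmoid), exposed in the layer constructors.

`train_cnn()` trains with Adam (learning rate 8e-4) under binary
cross-entropy: a stratified holdout (default 0.2) is set aside, k-fold
cross-validation (default 10) runs on the remainder with early stopping
on each validation fold, and a final model trained on the full remainder
is scored on the holdout. The engine is written in R with batched
im2col convolutions (one BLAS matrix product per layer and batch);
epochs and batch size default to 12 and 32 with patience 3 — unstated
in any reference, so chosen as ordinary small-data training settings.
Desk-scale runs use proportionally reduced inputs (e.g. 60×80) with the
shape chain re-inferred; the tests train ~200-image problems in minutes
on one CPU. `build_transfer_head()` emits the dense 256 → 32 → 1 head
for a pretrained backbone; downloading backbone weights is outside the
package's scope (and its tests).

## Pipeline orchestration

`run_pipeline()` chains simulate → preprocess → features → select →
train-ml (→ train-cnn, opt-in) with per-stage artifacts (CSV/JSON) and a
manifest carrying the configuration, its hash, the seed and metric
summaries; a rerun with the same configuration reproduces the feature
table bit-for-bit. `pipeline_config()` round-trips through YAML. The
package's functions are the interface; the pipeline runner is the
programmatic equivalent of a command-line driver.

## Numerical conventions and limitations

* Determinism: every stochastic step is seeded through an isolated RNG
  scope (`withr::with_seed`); cohort generation, selection, grid search
  and CNN training are reproducible given a seed and single-threaded
  BLAS.
* Quantiles are type-7 throughout; STD is population (divisor N).
* Band boundaries in the distribution summary place exactly-10 Hz in
  the 10–20 band and exactly-20 Hz below the ">20" band.
* Degenerate cases: empty signals, single-class tables, all-constant
  scalograms and impossible layer chains raise classed conditions
  (`cardiowave_*`) rather than silent results.
* Test problem sizes (e.g. 64-Hz sampling for the cohort suites,
  60-s recordings, 60×80 CNN inputs) are chosen as the smallest sizes at
  which the asserted properties are stable; they are stated in the test
  code itself.
* The generator's beat model is a sum of windowed sinusoids — it has no
  valve mechanics, respiration coupling, ECG timing or hemodynamics, and
  its amplitude units are arbitrary. Results on it validate the
  pipeline, not clinical performance; empirical mode decomposition and
  beat-level segmentation are deliberately out of scope.
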