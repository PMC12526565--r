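---
title: "Bimodal fall detection with decision-level fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal fall detection with decision-level fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fallfuse)
```

## The detection problem

fallfuse detects falls in nighttime home monitoring from two loosely
synchronized streams: a waist-mounted 6-axis IMU (tri-axial acceleration in
g, tri-axial angular velocity in °/s, 50 Hz) and a camera whose frames have
already been reduced to 33 two-dimensional skeletal landmarks per frame
(normalized coordinates plus a visibility score, 30 fps). Single-modality
detectors fail in complementary ways — inertial detectors false-alarm on
brisk but benign transitions (sitting down hard, rolling over), vision
degrades under occlusion and darkness — so the package processes the two
streams independently and only fuses their *decisions*.

## The inertial branch: reconstruction-error anomaly detection

Preprocessed windows are scored by an LSTM autoencoder trained **only on
non-fall motion**. The encoder stacks two LSTM layers (128 hidden units each
by default); the latent code is the concatenation of both layers' final
hidden states (256-dimensional). A symmetric two-layer LSTM decoder receives
the latent code repeated at every timestep, and a dense layer maps the
concatenated decoder states (256) back to the 6 channels.

The anomaly statistic for window $n$ is the reconstruction error

$$\mathrm{MSE}(n) = \frac{1}{T} \sum_{t=1}^{T} \lVert x_n(t) - \hat x_n(t) \rVert^2, \qquad T = 60,$$

where the norm is the squared Euclidean norm of the 6-channel residual. We
deliberately do **not** divide by the number of channels: the alternative
convention rescales the calibrated threshold by exactly the same factor, so
detection behaviour is unchanged; the convention used is fixed here and in
`fd_reconstruction_mse()`.

A window is flagged abnormal when $\mathrm{MSE}(n) > \tau$ (strict), where
$\tau$ is the 95th percentile (configurable) of the *training* reconstruction
errors, computed with the linear-interpolation percentile convention
(`stats::quantile` type 7) — the convention matters at small calibration
sizes and is therefore pinned. The normalized anomaly score is
$s_\mathrm{anomaly} = \min(\mathrm{MSE}(n)/\tau,\ 1) \in [0, 1]$.

**Preprocessing order.** Each channel is band-passed (4th-order Butterworth,
0.2–20 Hz, applied forward–backward so the effective order doubles and the
phase is zero) and *then* z-scored. Normalizing first would be undone by the
filter's DC rejection, which re-centres every channel. The z-score moments
come from the training partition (`fd_train_stats()`) and are reused
verbatim at test time, so held-out data never leaks into normalization.
Windows are 60 samples (1.2 s) with 50% overlap; incomplete trailing windows
are dropped rather than padded.

## The vision branch: posture cue and pose Transformer

Per frame, landmarks with visibility strictly above 0.5 are converted to
pixels ($x^{pix} = x^{norm} w$, $y^{pix} = y^{norm} h$, unrounded) and
bounded; the box aspect ratio $\rho = \text{width}/\text{height}$ gives a
coarse posture cue: $\rho > 1$ (strict) is prone/horizontal, otherwise
upright. $\rho = 1$ exactly is *not* prone — the cue is meant to fire on
unambiguous horizontal bodies. A frame with fewer than two usable landmarks
is "occluded".

**Temporal vote.** A fall posture is confirmed only after 30 strictly
adjacent prone frames (1 s at 30 fps). Occluded and upright frames reset the
run; an optional `occlusion_gap` tolerates short dropout bursts without
counting them toward the run (default 0, i.e. strict adjacency).

**Sequence classifier.** Non-overlapping 30-frame segments are flattened to
30 × 66 feature matrices (33 landmarks × 2 coordinates) and classified by a
Transformer encoder: learned 66→256 input projection, additive sinusoidal
positional encoding, four pre-norm encoder layers with 8-head self-attention
and a feed-forward width of 4× the model dimension, mean pooling, and a
2-logit softmax head. All of it — forward pass, backpropagation, Adam — is
implemented natively in base R matrix algebra, because the networks *are*
the method here; gradient correctness is enforced by finite-difference
tests. Training uses cross-entropy with inverse-frequency class weights
(fallen segments are a small minority of any recording), Adam at learning
rate 1e-4 with cosine annealing, batch 64, up to 40 epochs, early stopping
after 5 stagnant validation epochs, on a stratified 70/15/15 split. A
constant-rate recipe (3e-4) is selectable via `schedule = "constant"`.

**Gating.** The emitted vision probability is the transformer's fallen-class
probability, passed through unchanged when a confirmed prone streak overlaps
the segment's 1-s span and multiplied by 0.5 otherwise (`"gated"`, the
default). `"raw"` and `"hard_and"` modes exist for ablation.

## Decision-level fusion

Per 1-s epoch, the vision probability is paired with the maximum anomaly
score among IMU windows centred within ±0.6 s of the segment centre (the
1.2-s windows start every 0.6 s, so aligned streams always pair; pairing is
by timestamps, never by index, because the streams carry independent clock
offsets). The label is:

* **FALL** if $p_\mathrm{fall} > \alpha$ *and* $s_\mathrm{anomaly} > \alpha$
  (strict, $\alpha = 0.70$),
* **LOW_CONFIDENCE** if exactly one exceeds $\alpha$,
* **NORMAL** otherwise.

A missing IMU score can never produce FALL — the rule is conjunctive.
LOW_CONFIDENCE is an output label only; no escalation logic is attached.

**The trainable fusion head.** The threshold rule has no parameters, yet
few-shot personalization needs a trainable fusion stage. The package uses a
small 2→8→1 MLP (33 parameters, far below the 5k budget that makes
on-device adaptation cheap) whose first two hidden units are initialized as
sharp threshold detectors at $\alpha$, so the fresh head reproduces the AND
rule everywhere except a ±0.05 band around the threshold; the remaining
units start near zero and provide fine-tuning capacity. The pure rule
remains the default inference path.

**Fine-tuning recipe.** Fine-tuning runs exactly 50 full-batch Adam
iterations. The default learning rate is 0.05: Adam's per-parameter step is
approximately the learning rate, so 50 iterations at 1e-4 would move any
parameter by at most ~5e-3 — far too little to move a decision boundary of
a head whose parameters are O(1)–O(10). The rate is exposed as an argument
for sensitivity studies.

## The synthetic cohort simulator

No public recording of this acquisition protocol exists, so the simulator
is a first-class, tested module that carries the statistical structure the
method assumes, built from piecewise kinematic templates:

* **Falls** (forward/backward/lateral): quiescent upright phase → descent
  (~0.8 s, trunk angle 0→90°, free-fall-like dip in measured acceleration)
  → impact (Gaussian impulse, peak drawn uniformly from 2–6 g times a
  per-subject multiplier) → stillness on the floor. The landmark cloud
  rotates from tall to wide and drops to floor level in the image.
* **ADLs**: lying down (slow rotation to *bed* height), rolling over,
  sitting up and standing up (brisk sub-1.5 g transients — the inertial
  branch's natural false-positive source), walking (periodic gait
  oscillation, never prone).

Nuisances: additive Gaussian sensor noise, landmark jitter, i.i.d.
per-landmark visibility dropouts (default 5%, emulating sub-5-lux
occlusion) with an optional burst mode, a constant per-stream clock offset
(≤100 ms, emulating loose NTP synchronization) plus bounded per-sample
timestamp noise. Per-subject kinematic modifiers (stature, descent speed,
impulse magnitude) are drawn once per subject. Everything is seeded:
identical (script, noise, seed) triples are byte-identical.

The default cohort mirrors the target protocol — 16 subjects × 30 two-minute
trials, half falls — totalling 16 h. Signal amplitudes are stated in
`fd_noise_config()` as the package's choices; they are not claimed to match
any particular device.

**Ground truth.** The scripted `event_interval` spans the fall phase
(descent onset through early rest) and is used to *exclude* windows from
autoencoder training. The per-epoch evaluation truth is the narrower **event
core** (`fd_event_core()`): impact −0.4 s to impact +1.0 s, the second a
human annotator would mark as "the fall". The vision branch is trained on
the fallen *state* (body horizontal at floor level, known per frame for
simulated trials), which is what a pose classifier can actually see.

What the simulator does **not** emulate: photorealistic appearance,
biomechanical fidelity beyond the cue structure, multi-person scenes,
elderly-specific kinematics (slow or seated collapses), real pose-estimator
error correlations. Passing tests therefore show that the pipeline detects
the cue structure the method is designed around — not that it would reach
any particular accuracy on real recordings.

## Evaluation protocols

* **LOSO.** One fold per subject: the autoencoder (non-fall windows only),
  threshold and transformer are re-trained from scratch on the remaining
  subjects; all of the held-out subject's trials are scored per 1-s epoch.
  Unimodal baselines are thresholded on the same epochs
  ($s_\mathrm{anomaly} > \alpha$; $p_\mathrm{fall} > \alpha$).
  Micro-averaging pools confusion counts across folds before computing
  rates. For binary metrics, LOW_CONFIDENCE counts as **not-FALL** (the
  conservative mapping; switchable in `fd_confusion()`). Undefined ratios
  are reported as `NA`, never silently 0.
* **Confidence intervals** across folds use Student's t
  ($\bar x \pm t_{0.975,\,n-1}\, s/\sqrt n$; 2.131 at 16 folds);
  between-method differences use classic paired two-sided t-tests with
  explicit degenerate handling for zero-variance differences.
* **Few-shot personalization.** Per subject and per $K \in \{1,...,10\}$: a
  class-stratified calibration set of exactly $K$ labeled 1-s sequences is
  drawn without replacement, only the fusion head is fine-tuned (the
  encoders are frozen — the head never sees anything but the two branch
  scores), and F1 is evaluated on the disjoint remainder. Fold-mean F1 per
  $K$ is reported with its t-interval, averaged over replicate draws.
* **Learning curve.** For cohort sizes $m$ in a grid, random $m$-subject
  subsets are evaluated by LOSO *within the subset* (each fold trains on
  $m-1$ subjects), 10 draws per size. The mean-F1 points are fitted with the
  saturating exponential $F1(n) = a - b e^{-cn}$ (nonlinear least squares;
  initialization $a_0 = \max$ mean, $b_0 = a_0 - \min$ mean, $c_0 = 0.3$);
  the asymptote CI comes from a seeded bootstrap (1000 resamples) over the
  per-size draws, and saturation is declared when the fitted gain from
  $m = 12$ to $m = 16$ is below 0.5 percentage points.

## Numerical and design choices

* Percentile convention: linear interpolation (type 7); raising the
  percentile never lowers τ.
* Strict inequalities throughout (abnormality, prone rule, fusion
  thresholds); boundary cases are tested explicitly.
* Zero-variance channels, empty calibration sets, single-class training
  data, incomplete segments and out-of-range sensor values are rejected
  with informative errors; calibration on fewer than 20 errors degrades
  with a warning rather than failing.
* All stochastic steps take explicit integer seeds; nested sub-seeds are
  derived arithmetically (`fd_subseed`) and stay below 2^31.
* Adam is the optimizer everywhere; the forget-gate bias starts at +1; the
  transformer uses pre-norm residual blocks (stable without a warm-up
  schedule at these depths).

## Scaled-down study sizes

The package defaults reproduce the reference operating point (128-unit
LSTM layers, 4-layer/8-head/256-dim transformer, 16 × 30 × 120 s cohort).
The bundled desk-scale study — used by the test suite and
`scripts/acceptance.R` — runs 8 subjects × 10 trials of 20 s with
`fd_config_small()` (8-unit LSTM layers, one 2-head transformer layer at
model dimension 32, seeded training-set caps of 600 windows / 500
segments), which completes LOSO in a few minutes on one CPU while leaving
every signal-processing, thresholding and fusion parameter at its
reference value.

## Known limitations

* The conjunctive rule bounds fused recall by each branch's recall; epochs
  at the edges of the event core are routinely missed by one branch, so
  desk-scale recall sits well below what a full-scale cohort and models
  could reach. The FPR ordering (fused below both baselines) is the robust,
  tested property.
* Pure base-R training is CPU-bound; the full-size architecture is
  practical for inference and small studies, not for large cohorts.
* The simulator's nuisances are independent across frames and channels;
  real occlusions and pose-estimation errors are temporally correlated
  beyond what the burst mode captures.
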