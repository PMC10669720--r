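---
title: "Classifying heart murmurs with capsule networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying heart murmurs with capsule networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murmurcaps)
```

## The problem

Cardiac auscultation produces phonocardiograms (PCGs): recordings of the
heart's acoustic activity at the chest surface. A normal cardiac cycle is
dominated by two low-frequency transients — S1 (start of systole) and S2
(start of diastole), both well below 200 Hz. A murmur is additional
band-limited sound energy, typically between S1 and S2, caused by turbulent
blood flow; detecting it reliably is a screening task with real clinical
value. `murmurcaps` implements an end-to-end binary classifier
(normal / abnormal) for 5-second PCG clips, built around a capsule neural
network operating on MFCC spectra.

## Preprocessing

Four steps, applied in this order:

1. **Segmentation** (`segment_pcg`): non-overlapping clips of a fixed
   duration (default 5 s). A trailing remainder shorter than one clip is
   discarded; stereo input is mixed to mono by channel averaging, since the
   network input is single-channel.
2. **Downsampling** (`downsample_pcg`): polyphase FIR resampling
   (`signal::resample`) to the 2 kHz model rate. The FIR low-pass runs
   before rate reduction, so the sub-1 kHz band that carries S1, S2 and
   murmur energy is preserved; upsampling is refused.
3. **Normalization** (`normalize_pcg`): per-segment peak scaling to
   [-1, 1]. It is idempotent; an all-zero segment passes through with a
   warning rather than producing NaNs.
4. **MFCC extraction** (`mfcc_spectrum`): Hann-windowed STFT, power
   spectrum, triangular mel filter bank, log, orthonormal DCT-II.

The MFCC configuration is a declared convention of this package: the
architecture constrains only the output shape (128 coefficients x 16
frames for a 5-s, 2 kHz clip), not the analysis parameters. The defaults
are 128 mel filters spanning 20–1000 Hz (the band the 2 kHz rate can
represent, with a low cut below which chest-surface recordings are
dominated by sensor rumble), frame length 1024 samples (~0.5 s, long
enough to resolve the mel bands at low frequency), hop 625 samples,
centred framing with reflection padding, and all 128 DCT coefficients
retained. Centred framing at hop 625 admits 17 frames from 10,000
samples; the final frame is truncated to give exactly 16, and a shape
assertion guards the contract. Extraction is a pure function of
(samples, configuration): identical bytes give bit-identical matrices.

Other clip lengths (1/3/10 s) carry their own presets (`segment_preset`)
pairing an MFCC configuration with the matching network geometry; frame
counts for those variants (4/10/32) are package conventions chosen so the
convolution chain stays valid.

## The capsule network

The network is: valid-padding strided convolution (ReLU) → a second
convolution whose feature maps are partitioned into *primary capsules* →
iterative dynamic routing to two *digit capsules* (one per class) → class
scores as capsule lengths, plus a fully connected decoder that
reconstructs the input from the selected digit capsule.

A capsule is a vector whose orientation encodes the pose of a feature and
whose length encodes the probability that the feature is present. Lengths
are kept in [0, 1) by the squash nonlinearity

$$\mathrm{squash}(v) = \frac{\lVert v\rVert^2}{1+\lVert v\rVert^2}\,
\frac{v}{\lVert v\rVert},$$

which preserves direction, maps zero to zero, and is strictly increasing
in the input norm.

Routing by agreement couples each primary capsule $i$ to each digit
capsule $j$: prediction vectors $u_{j|i} = W_{ij} s_i$; couplings
$c_{ij} = \mathrm{softmax}_j(b_{ij})$ with logits initialized to zero;
weighted sums $s_j = \sum_i c_{ij} u_{j|i}$; outputs
$v_j = \mathrm{squash}(s_j)$; and logit updates
$b_{ij} \leftarrow b_{ij} + u_{j|i}\cdot v_j$, iterated R times (default
5). The softmax runs over the digit axis, so each primary capsule's
couplings sum to 1. The order within an iteration — couplings from the
current logits, then outputs, then the logit update — resolves the
circular dependence the update rule leaves implicit. With R = 1 the
procedure reduces to a uniformly weighted average followed by squash.

Classification digitizes the digit-capsule lengths:
class $c$ is declared present iff $\lVert v_c\rVert^2 > T^2$ (strict),
with threshold $T = 0.5$. Training minimizes the margin loss

$$L = \sum_c T_c \max(0, m^+ - \lVert v_c\rVert)^2
 + \lambda (1 - T_c)\max(0, \lVert v_c\rVert - m^-)^2$$

with $m^+ = 0.9$, $m^- = 0.1$, $\lambda = 0.5$. These constants and $T$
are the canonical capsule-network values; the loss above matches the
canonical formulation symbol for symbol, so those defaults are adopted
and exposed as configuration rather than hard-coded.

Under the default 5-s preset the layer chain is 128×16×1 → conv1 (256
filters, 9×9, stride 2) → 60×4×256 → primary-capsule conv (256 filters =
16 channels × dimension 16, kernel 4, stride 1) → 57×1×256 → 912 primary
capsules of dimension 16 → 2 digit capsules of dimension 16. The
parameter audit (`count_params`, `audit_params`) reproduces the per-layer
trainable-parameter counts analytically: 20,992 / 1,048,832 / 466,944 /
6,329,344 (decoder) and 7,866,112 in total.

### Decoder

Only the decoder's parameter count and output shape are architecturally
constrained. A fully connected stack 32 → 1024 → 2048 → 2048 (ReLU
hidden, sigmoid output, reshaped to 128×16×1) is the unique natural
two-hidden-layer geometry meeting that count: 33,792 + 2,099,200 +
4,196,352 = 6,329,344. Its input is the digit-capsule block masked to a
single class — the true class during training, the predicted class at
inference. Because MFCC log-energies are unbounded while the sigmoid
output lives in (0, 1), the reconstruction target is the input spectrum
min–max scaled to [0, 1] per sample. The total training loss is
margin loss + `w_rec` × mean reconstruction SSE, with `w_rec = 5e-4` by
default; `w_rec = 0` trains on margin loss alone, which is the loss the
evaluation reports either way.

### Gradients

No automatic-differentiation backend is used: the backward pass is
hand-derived reverse mode through the decoder, both squashes, the
routing weighted sum, the capsule reshape and both convolutions, and is
checked against central finite differences in the test suite. One
convention matters: the coupling coefficients produced by the forward
routing iterations are treated as constants in the backward pass.
With a single routing iteration they *are* constants (softmax of zero
logits), and the analytic gradient is exact — the finite-difference test
asserts this. With more iterations the couplings depend weakly on the
parameters and the detached gradient is an approximation (observed
within a few percent of finite differences on small instances); the
optimizer contract — that the margin loss decreases and the separable
synthetic task is learned — is what the training tests assert. This is
the standard trade-off in capsule-network implementations and keeps the
backward pass linear in the number of routing iterations.

Weights are initialized from scaled normal distributions (He-style for
convolutions and decoder, smaller scale for the per-pair digit
transforms, which carry no bias — the printed digit-capsule parameter
count forces the no-bias choice). Initialization and training restore
the caller's RNG state and are fully reproducible from their seeds.

## Training and evaluation

`fit_capsnet` runs minibatch Adam (default batch 8 per the 5-s preset;
initial learning rate 0.0025, 100-epoch cap, 5 routings). Three
learning-rate policies are provided, replayed deterministically from the
validation-loss history by `lr_schedule`:

* **plateau** (default): multiply the rate by 0.15 after 3 consecutive
  epochs without validation-loss improvement;
* **decay**: start at 0.005 and multiply by 0.1 at fixed intervals. The
  interval is not architecturally constrained; every 30 epochs is the
  package default;
* **fixed**: constant 0.0025.

Early stopping halts training when the gap between validation and
training margin loss exceeds 15%. The gap is interpreted *relative to
the training loss* — scale-free across loss magnitudes — with an
absolute-gap mode available in `train_config`. When training stops, the
weights of the best-validation-loss epoch are restored (a deliberate
default; the alternative of keeping the final weights is a one-flag
change). When no validation set is supplied the training set stands in
and the gap is identically zero, so only the epoch cap stops training.

Evaluation treats **normal as the positive class**: TP counts normal
recordings predicted normal and TN abnormal predicted abnormal, so
precision = TP/(TP+FP), recall = TP/(TP+FN), abnormal precision =
TN/(TN+FN), specificity = TN/(TN+FP). A zero denominator yields `NA`
(undefined), never silently 0. The continuous score is the normal-class
capsule length; the confusion matrix thresholds its square at $T^2$, and
the ROC curve sweeps every observed score as a threshold, with AUC by
the trapezoidal rule (cross-checked in tests against the Mann–Whitney
formulation and against pROC). Segment-level metrics are primary; a
majority-vote aggregation to recordings is available
(`evaluate_model(by_recording = TRUE)`) but is secondary.

## The synthetic phonocardiogram generator

`generate_recording` emulates exactly the structure the classifier
assumes: quasi-periodic cycles at a heart rate drawn uniformly from
55–110 bpm with ±5% per-cycle jitter (to avoid degenerate periodicity);
a Gaussian-windowed 70 Hz S1 burst at each cycle start and an 0.8-amplitude
120 Hz S2 burst at 35% of the cycle; for the abnormal class, 150–700 Hz
band-limited noise filling the systolic S1–S2 window at 0.4 amplitude
relative to S1; white noise at 2% of S1; peak scaled to 0.9. The murmur
band sits above the S1/S2 fundamentals and below the Nyquist limit of
the 2 kHz model rate, which makes the two classes separable by design: a
trivial 150–700 Hz band-energy threshold recovers the labels with ≥95%
accuracy, so the learning tests are well-posed. The same random draws
are consumed whether or not the murmur is added, so an abnormal
recording with `murmur_amplitude = 0` is sample-identical to its normal
counterpart — a useful null for testing.

What the generator does **not** emulate: diastolic or continuous
murmurs, split heart sounds, S3/S4, respiratory and sensor noise
structure, inter-patient variability of spectral envelopes, or recording
hardware coloration. Passing the learning tests therefore shows that the
pipeline trains and generalizes on signals with the assumed structure —
it says nothing about accuracy on clinical recordings, which depends on
data this package does not ship.

## Numerical choices and degenerate inputs

* Convolution is cross-correlation (no kernel flip) with valid padding
  and floor division for output sizes — forced by the 128 → 60 mapping
  under kernel 9, stride 2.
* `squash(0) = 0` by convention (the limit value); its backward at 0 is
  likewise 0.
* Softmax subtracts the row maximum before exponentiation.
* All-zero segments: normalization passes them through with a warning,
  and every MFCC frame of silence yields the identical coefficient
  column (`log(1e-10)` floor in the filter-bank energies).
* Digitization at exactly the threshold is 0: the inequality is strict.
* Non-finite losses abort training with a diagnostic rather than
  propagating.
* Ties in the decoder mask (equal capsule lengths) resolve to the
  first class, via `which.max`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data
at sizes chosen to exercise every code path at interactive speed: the
routing oracle comparison uses 100 random instances of up to 16 primary
capsules; the learning check trains the reduced network (32 conv1
filters, capsule dimension 8, 2 routing iterations, decoder 64/128) on
200 recordings per class with 50 per class held out, for at most 30
epochs — it typically converges to ≥95% held-out accuracy within one or
two. The full 7.9M-parameter default preset is exercised for shape and
parameter audits and single forward passes; training it end to end is
feasible with this package but is a workload for real datasets, not for
a test suite.

## Known limitations

* The detached-coupling gradient (above) is approximate for R > 1.
* Training is pure R; a full-scale run on thousands of recordings is
  hours, not minutes. The architecture audit, preprocessing and
  inference are fast.
* The PhysioNet-style reader expects the simple `wav + label CSV`
  layout; it does not fetch or validate the external database.
* Binary classification only; no murmur sub-typing, no heart-sound
  state segmentation (S1/systole/S2/diastole), no denoising beyond
  anti-aliasing.
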