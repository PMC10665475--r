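---
title: "Detecting breathing events while driving: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting breathing events while driving: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respfusion)
```

respfusion detects breathing events in multichannel in-cabin recordings.
Four sensor channels observe the driver's chest movement with very
different noise characteristics — a piezoelectric pressure sensor in the
seat belt, a 3-axis accelerometer on the seat belt, and two scalar
traces extracted from fixed video regions of interest (belt and chest) —
while a second, seat-mounted accelerometer observes vehicle noise only
and a chest belt provides the ground truth. This vignette explains the
models the package implements, the numerical choices behind them, and
what the synthetic study used in the tests does and does not establish.

## The detection problem

All channels are brought to a unified 200 Hz timeline and cut into
sliding windows of 201 samples (about one second). A window is a
*positive* snippet if a reference breathing peak falls within a
tolerance of its center (default 50 samples, i.e. 0.25 s), and the task
is binary snippet classification. Training windows advance 11 samples at
a time (overlap 190); test windows advance one sample (overlap 200), so
prediction sweeps the whole recording densely. Evaluation is
leave-one-subject-out (LOSO): a model never sees the tested subject.

The score is the average of positive predictive value and sensitivity,
in percent:

$$P = 100 \cdot \frac{PPV + S}{2}, \qquad
  PPV = \frac{TP}{TP+FP}, \qquad S = \frac{TP}{TP+FN}.$$

When a denominator is zero the affected term is defined as 0 (flagged in
the record); this is the conservative choice — an all-negative predictor
scores 0, not "undefined". `P` is reported per (subject, scenario) cell,
averaged over folds within a scenario, and scenario means are averaged
into a per-strategy `Mean_P`. Rounding (2 decimals, half away from zero)
happens only at report time.

## Reference-channel spectral suppression

The seat-belt accelerometer mixes respiration with vehicle noise; the
seat accelerometer sees, to good approximation, the vehicle noise alone.
Both 3-axis sensors are band-pass filtered to the respiration band
(default 0.1–0.7 Hz, i.e. 6–42 breaths/min) and collapsed to one trace
each by projecting onto the first principal component of the axis cloud.
Denoising then happens per frequency bin: with $X_1$ the spectrum of the
belt combination and $X_2$ of the seat combination,

$$SF(k) = \exp\!\left(-\frac{|X_2(k)|}{\mu(|X_1|)}\right), \qquad
  X_{supp}(k) = SF(k)\, X_1(k),$$

and the denoised time signal is the inverse transform of $X_{supp}$.
Bins that are loud in the noise reference are attenuated exponentially;
bins the reference is silent about pass unchanged ($SF = 1$). Because
$SF$ depends only on magnitudes it is conjugate-symmetric for real
inputs, so the inverse transform is real up to round-off; the residual
imaginary part is asserted below $10^{-9}$ of the signal scale and then
discarded.

### Why the suppression is windowed on full recordings

Applied as a single full-record transform, the formula is numerically
degenerate for long, narrowband-filtered signals, for two compounding
reasons:

1. After a band-pass to 0.1–0.7 Hz almost every bin of $X_1$ is empty,
   so the normalizer $\mu(|X_1|)$ — a mean over *all* bins — is diluted
   by a factor of roughly $f_s / (2 \cdot \text{bandwidth})$, about 80
   at 100 Hz.
2. An untapered transform of a strong narrowband component leaks a
   sidelobe pedestal across the whole band; those pedestal magnitudes in
   $|X_2|$ are then tens of times $\mu(|X_1|)$, and
   $\exp(-|X_2|/\mu)$ underflows to zero across the entire pass band —
   including the respiration bin. The surviving output is whatever
   out-of-band residue had a quiet reference, i.e. noise.

`spectral_suppress()` therefore offers a windowed form — Hann-tapered
segments (default 20 s) with half-window hop, suppressed per segment and
overlap-added; both channels are reflection-padded so every retained
sample has full taper coverage. The taper suppresses the leakage
pedestal by orders of magnitude and restores per-window ratios
$|X_2(k)|/\mu(|X_1|)$ of order one, which is the regime in which the
exponential factor discriminates between noisy and quiet bins instead of
zeroing everything. `denoise_accelerometer()` uses the windowed form for
any record longer than `suppress_window_s` (default 20 s); the
single-transform form remains available (`suppress_window_s = 0`) and is
the reference behaviour for short signals, where the unit tests verify
it bin-for-bin against a brute-force DFT oracle. On simulated city
driving the windowed suppression raises the correlation between the
accelerometer combination and the true chest movement relative to
band-pass + PCA alone; the acceptance suite measures this gain across
ten seeded subjects and asserts a mean above +0.05.

Related numerical choices: the Butterworth band-pass (order 2, applied
forward and backward so it is zero-phase and does not shift breathing
peaks) operates on odd-reflection-padded input, because with a 0.1 Hz
band edge the filter transient is many seconds long and would otherwise
leak low-frequency energy across the record. The first principal
component's sign is fixed by requiring a positive loading on the axis of
largest variance, so runs are reproducible; constant (rank-0) input
yields a zero trace with a logged warning rather than an error.

## Video traces

Each frame contributes one sample: the arithmetic mean of the green
channel over a fixed region of interest, i.e.
$\text{color}_{avg} = \frac{1}{w h}\sum_{i=1}^{w}\sum_{j=1}^{h}
\text{Pixel}_{i,j}$. The default rectangles — belt
(x 701, y 550, w 10, h 190) and chest (x 401, y 550, w 400, h 190) on a
1280×720 frame, 0-based coordinates — are configurable.
`verify_roi()` re-anchors an ROI before extraction by searching integer
shifts within a radius (default 5 px) for maximal intensity variance,
the high-contrast chessboard pattern on the belt being the expected
anchor; if even the best shift has negligible contrast the nominal ROI
is kept with a warning. Contrast maximization was chosen over corner
detection because it needs no feature model and is exact on the
synthetic frames used to test it.

## Fusion models

Every strategy is built from one convolutional branch type: a bank of 4
filters of length 20 samples, ReLU, dropout 0.5 (training only),
max-pooling of width 4, flattened. (The paper-level architecture fixes
the filter bank, dropout and the sigmoid output; the conv-layer
nonlinearity is not specified anywhere, and ReLU is the standard choice
for this architecture family.) The strategies differ only in topology:

* **early** — one branch ingests all selected channels jointly (the
  filters span the channel dimension);
* **signal-based late** — one branch per signal; features are
  concatenated before the dense layer;
* **sensor-based late** — two independently initialized branches per
  signal, concatenated likewise (a wider feature set);
* **hybrid** — no network of its own: the elementwise 2-of-3 majority
  vote over the binary outputs of the other three.

A single dense sigmoid unit produces the score; labels are scores
thresholded at 0.5. Training is minibatch Adam (learning rate $10^{-3}$,
batch 64, all configurable) on the binary cross-entropy. Because the
center-tolerance labelling makes positives a minority (roughly
$2\cdot 50 + 1$ out of one breath period ≈ 13% at 15 breaths/min),
classes are weighted inversely to frequency by default; without this a
degenerate all-negative predictor is a strong local minimum. Everything
— initialization, shuffling, dropout — derives from one seed, and
repeated runs are bitwise reproducible on CPU; the engine (im2col +
BLAS matrix products, hand-derived gradients checked against finite
differences in the tests) is part of the package and has no external
runtime dependency.

For dense step-1 test prediction the package evaluates the convolution
once over each full trace and gathers per-window pooled features from a
running maximum; this is algebraically identical to per-snippet forward
passes (ReLU commutes with max; dropout is off at prediction) and the
tests assert exact score equality. It is what makes sweeping ~100,000
test windows per fold cheap.

## The synthetic study

The simulator generates what the pipeline needs to be tested end to end
with known truth. One subject is a quasi-periodic chest movement: base
rate 12–20 breaths/min (drawn without duplicates across subjects), slow
sinusoidal rate wander (3–8%), waveform $\sin\theta - 0.3\cos 2\theta$
whose maximum sits exactly at phase $\pi/2$ — so ground-truth peaks are
written down by construction, not detected. Channels at native rates
(hub 100 Hz, video 10 fps, exercising the resampling path):

* piezo: respiration + 8% vehicle noise + sensor noise;
* belt accelerometer: per-axis respiration gains (0.9, 0.5, 0.25) plus
  the shared vehicle noise (gains 1.0, 0.8, 0.6);
* seat accelerometer: shared vehicle noise only (gains 0.9, 1.0, 0.7)
  plus sensor noise — no respiration;
* video traces: lagged (0.1–0.3 s), rescaled respiration with slow
  illumination drift;
* reference: respiration with 1% noise.

Vehicle noise is modeled as three amplitude-modulated narrowband
resonances — body sway at 0.35–0.6 Hz (inside the respiration band),
suspension at 1.2–2.5 Hz, engine/road order at 8–15 Hz — over a weak
flat broadband floor, plus Poisson road-bump transients with a Gaussian
envelope around a 2–5 Hz carrier. Road vibration in a real car is
resonance-dominated, and this structure is also the regime in which a
reference-channel method can work at all: a spectrally flat noise floor
comparable to the signal would drive $SF$ toward zero uniformly and no
per-bin scheme could separate the two. The scenarios differ only in
noise gain, transient rate and drift (highway 0.7/1/0.2, city 1.0/4/0.3,
countryside 1.3/6/0.4) — ordered by road roughness.

What passing tests on this simulator shows: that every stage is wired
correctly, that the suppression formula helps exactly where its premise
(a co-located noise-only reference with structured noise) holds, that
the fusion models learn the event-centering task well above the ~50
chance level of the P metric, and that the whole chain is deterministic.
What it does not show: performance on real driving data — the simulator
has no talking, posture shifts, illumination changes, belt slippage or
sensor dropouts, and its subjects differ far less than real ones; scores
on it are accordingly much higher than published in-vehicle results.

## Problem sizes and defaults

The package-level study used by the acceptance checks is 6 subjects × 3
scenarios × 3 minutes with 5 training epochs of the signal-based late
fusion — small enough to run on one CPU in minutes, large enough that
each fold trains on ~49,000 windows and is tested densely on ~107,000.
All pipeline constants live in one `pipeline_config()` object: band
edges (0.1–0.7 Hz), median kernel (5 samples — removes single-sample
spikes without flattening a breath), unified rate (200 Hz), snippet
geometry (201 / 190 / 200), label tolerance (50 samples), peak detection
(minimum spacing 1.5 s ≙ 40 breaths/min cap; prominence 0.1 × IQR of the
trace after a zero-phase 2 Hz smoothing low-pass, which exists because
raw measurement noise otherwise produces spurious local maxima whose
topographic prominence exceeds any scale-free threshold), model
hyperparameters, and the seed. Amplitude normalization to $[-1, 1]$ is
per recording, preserving relative amplitudes across snippets; a
constant trace maps to zeros with a warning.

## Known limitations

* The P-to-"usable driving time" restatement in `usable_time_report()`
  equates a classification score with a time fraction; the report labels
  it as an interpretation rather than a measurement.
* The hybrid vote can be worse than its best member on a given set;
  only the voting identity is guaranteed, and the tests assert nothing
  stronger.
* The windowed suppression assumes noise stationarity within ~20 s
  segments; a transient inside one window attenuates that window's band
  more than its neighbours'.
* `estimate_rate_bpm()` (merged positive runs per minute) is a
  convenience utility; the evaluation protocol scores snippet
  classification, not rate estimates.
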