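---
title: "Robust flight-call detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust flight-call detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Autonomous recording units (ARUs) capture nights of continuous audio in
which migrating birds leave short (50–150 ms) flight calls between 2 and
10 kHz. Two properties of the background noise defeat naive detectors:

* **Nonstationarity**: insect stridulation concentrated near 2–2.5 kHz
  and its second harmonic near 4–5 kHz is loudest at dusk and fades by
  roughly 10 dB over the night, while the call rate rises toward dawn. A
  classifier trained mostly on (abundant) dawn examples systematically
  misses dusk calls.
* **Nonuniformity**: each sensor sits in its own acoustic environment, so
  a detector tuned on some sensors mis-calibrates on others.

`flightcall` implements a detection stack that addresses the first
problem with an adaptive time-frequency frontend (PCEN) and the second
with a context-adaptive output layer, and ships a seeded synthetic-night
generator so the whole stack is testable end to end without field data.

## Time-frequency frontend

Audio is analyzed at 22,050 Hz with an STFT of window 256 (about 12 ms),
hop 32 (1.5 ms) and FFT length 1024, mapped onto 128 mel bands between
2 kHz (the lower edge of the thrush vocal range) and the Nyquist
frequency. Samples are held internally as unit-range floats and rescaled
to the full-scale 32-bit integer range before analysis so that the PCEN
constants below keep their conventional meaning. Two conventions are
deliberate:

* **No frame padding.** All analysis windows lie fully inside the
  signal and carry window-center times. Padding would synthesize an
  energy edge at t = 0 that the adaptive gain control would amplify.
* **Slaney-style mel filterbank**, area-normalized, the most common
  default in the field's software.

Per-channel energy normalization (PCEN) replaces the static log
compression of the mel spectrogram:

```
PCEN(t, f) = ( E(t, f) / (eps + M(t, f))^alpha + delta )^r  -  delta^r
```

where `M` is a low-pass smoothed version of `E`. The division is
per-band automatic gain control (AGC); the `(. + delta)^r - delta^r` map
is root dynamic-range compression. Two presets are provided: `indoor`
(`alpha` 0.98, `delta` 2, `r` 1/2, smoother support 400 ms), the
far-field speech recommendation, and `outdoor` (`alpha` 0.8, `delta` 10,
`r` 1/4, 60 ms), suited to bioacoustic scenes with skewed, loud
backgrounds and fast foreground modulations. With `alpha = 1` and small
`eps`, constant inputs of any level produce identical output — the
invariance that erases slowly varying background noise.

The smoother is a design choice the published equation leaves open: we
use a causal first-order IIR filter, `M(t) = (1-s) M(t-1) + s E(t)`,
with `s = (sqrt(1 + 4T^2) - 1) / (2T^2)` for a support of `T` frames,
initialized at the first frame (`M(1) = E(1)`) to suppress the onset
transient. A causal smoother keeps the frontend deployable in streaming
mode.

`magnitude_distribution()` quantifies the practical consequence: after
global standardization, log-mel magnitudes of insect-band noise are
strongly skewed while PCEN(outdoor) magnitudes are close to Gaussian.
The package's acceptance checks assert the direction of this comparison
on synthetic nights rather than any absolute skewness value.

## Long-term context features

The auxiliary representation `mu(t, q, f)` summarizes the background: 9
order statistics (permille, percentile, decile, quartile, median and
their upper mirrors — levels 0.1, 1, 10, 25, 50, 75, 90, 99, 99.9 %) of
the time-frequency magnitudes in a trailing 30-minute window (`T_CA`),
per frequency band, with 128 mel bands average-pooled in groups of 4
down to 32. The default sampling period is 450 s (8 frames/hour).
Windows are trailing (causal) so the first frames simply use whatever
audio exists; a window longer than the recording is truncated with a
warning. Quantiles use linear interpolation between order statistics
(type 7, R's default). Order statistics over half-hour windows are
insensitive to any single 150 ms call — by design, the context must
describe the environment, not the events.

`band_spl_trend()` is the matching diagnostic: median in-band energy per
30-minute segment in dB re full scale. Because segment medians sit at
segment centers, a linear ramp of `D` dB measured as a first-to-last
difference is biased by a factor `(S-1)/S` for `S` segments;
`estimate_decay_db()` removes that factor exactly.

## The context-adaptive network

The main branch is a compact CNN: three convolutional layers (24, 24, 48
kernels of 5x5; ReLU; strided 4x2 max pooling after the first two, so
the 104-frame clip is downsampled 16x in time), a 64-unit dense
embedding with an L2 penalty of 1e-3, and a sigmoid head. The auxiliary
branch takes one 9 x 32 context slice and applies 8 kernels of size
1 x 32 — weight sharing across quantile levels only, so each kernel acts
as a learned spectral template of background noise — giving 9 x 8 = 72
activations, then a dense layer to the same embedding width.

Four output-layer formulations connect main code `z` and auxiliary code
`z_aux`:

| formulation | output |
|---|---|
| baseline | `sigmoid(b + w.z)` |
| adaptive weights (AW) | `sigmoid(b + z_aux.z)` |
| adaptive threshold (AT) | `sigmoid(w_aux.z_aux + w.z)` |
| mixture of experts (MoE) | `sigmoid(b + sum_k softmax(alpha)_k s_k)` |

For MoE, codes reshape by `n = K m + k` (`K = 4` experts, `M = N/K`
mixture indices), `alpha_k = b_aux(k) + sum_m w_aux(m,k) z_aux(m,k)` and
`s_k = sum_m w(m,k) z(m,k)`. The mixture weights `w_aux(m,k)` are static
learned parameters; only `z_aux` varies with time (the printed form of
the gate equation carries a time index on the weights, but only a static
reading defines a trainable parameter). Each formulation contains the
static baseline as a special case, and the package asserts those
reductions constructively to 1e-6 over a thousand random codes. The AT
formulation is exactly a slowly varying detection threshold: for fixed
`tau`, `y(t) > tau` iff `sigmoid(w.z) > sigmoid(sigmoid^-1(tau) -
w_aux.z_aux)` — `adaptive_threshold_view()` returns that right-hand
side.

### Training

Binary cross-entropy, minimized with Adam (defaults: learning rate 1e-3,
betas 0.9/0.999, batch 32, early stopping on validation accuracy with
patience 20 when a validation split is given). Initialization is
Glorot-style uniform under a caller-supplied seed; training is bitwise
reproducible given the seed on a fixed platform. Validation splits must
not share sensors with training splits (leave-one-sensor-out), and the
trainer refuses them otherwise. Accuracy is the fraction of clips with
`|y - y_true| < 0.5`, strict, so a constant 0.5 output scores 0.

One pragmatic addition: a global affine standardization of each branch's
input (two scalars per branch, fit on the training set and stored in the
checkpoint). Log-mel features carry an additive offset of roughly +25
units that would otherwise park the sigmoid head deep in saturation at
small training budgets; standardization puts both frontends on an equal
footing. The gradients of every layer are verified against central
finite differences to 1e-4 relative error in the test suite.

### Gradient and pooling conventions

Convolutions are valid (no padding), exactly reproducing the published
receptive-field arithmetic (4 frames = 6 ms after one pool, 16 frames =
24 ms after two). Pooling drops trailing rows that do not fill a
receptive field (floor convention). The max-pool backward pass routes
the gradient to the first maximum in each cell; ties have measure zero
for real-valued features.

## Detection in continuous audio

The trained clip classifier slides over the recording with a 150 ms
window and 50 ms hop, producing the event detection function (EDF) at 20
frames/s; each value is stamped with the window-center time and windows
lie fully inside the recording. Because valid convolution commutes with
time shifts, the first convolutional layer is computed once per
recording and shared across the overlapping windows (the window-aligned
pooling grids fall in four phase classes); this is exactly equivalent to
window-by-window evaluation — asserted in the tests — and about three
times cheaper. Context-adaptive models embed each unique context frame
once (the context varies ~8 times/hour, the EDF 20 times/s).

Peaks are strict-left / weak-right local maxima above the threshold
(`y(t-1) < y(t) >= y(t+1)`), so plateaus and edge frames never fire.
With a minimum-spacing constraint (150 ms reproduces the classic
baseline; 0 disables it), suppression is greedy from the highest score,
ties broken by earlier time. With zero spacing, peaks can be as close as
two hops (100 ms).

## Event-based evaluation

Predicted and reference timestamps match when within 500 ms; the
matching is maximum-cardinality bipartite (any maximum matching gives
the same TP/FP/FN). Precision is 1 by convention when nothing is
detected; recall on an empty reference is an error, not a number. The
PR curve sweeps 100 thresholds by default; AUPRC integrates
trapezoidally over the recall axis after sorting, extending the curve to
recall 0 at the precision of its lowest-recall point (the published
metric names neither an interpolation nor an endpoint rule, so the rule
is stated here and asserted against a brute-force recomputation in the
tests). `segmented_recall()` reports recall per 30-minute segment and
per band (low = thrushes, 0–5 kHz; high = warblers and sparrows,
5–10 kHz) under one global matching.

## Augmentation

Geometrical data augmentation (GDA) draws 4 pitch shifts (uniform within
one semitone — the scale of natural vocal variability) and 4 time
stretches (log-uniform rate in 0.9–1.1) per clip; adaptive data
augmentation (ADA) adds 4 background-noise mixes per training sensor
(SNR uniform in -6 to +6 dB), giving 4 + 4 + 4x3 = 20 variants with
three training sensors. Exactly one effect applies per variant. Noise
sources must share the clip's dataset split, and ADA is refused for
context-adaptive configurations: mixing extraneous noise into a clip
without recomputing its 30-minute context features would deliberately
desynchronize the two branches. Pitch shifting resamples then restores
duration with a phase-vocoder time stretch (Hann analysis/synthesis,
75 % overlap, weighted overlap-add); the published experiments defer the
parameter ranges to prior work, so the ranges above are this package's
own, stated here once.

## The synthetic night generator

`night_spec()` / `synthesize_night()` emulate the statistical structure
the methods react to, not species-level acoustics:

* background: pink noise plus 2–3 amplitude-modulated harmonic clusters
  near 2–2.5 and 4–5 kHz (insect chorus), with per-sensor detuning and
  level offsets (default -3 to +3 dB across sensors), all decaying
  linearly in dB (default 10 dB over the night);
* events: an inhomogeneous Poisson process (thinning) whose rate ramps
  up over the night; each event is a linear-frequency chirp under a
  raised-cosine envelope — low band: 2–5 kHz downsweeps of 100 ms; high
  band: 5–10 kHz chirps of 50 ms — with log-normal peak amplitudes;
* ground truth: exact center times and band labels.

Everything is reproducible from `(spec, sensor)`. The background level
(`noise_sigma = tone_amp = 0.08`) was set so that a log-mel baseline
detector shows the qualitative regime of full-night field recordings —
early-segment recall clearly depressed relative to the late, quiet end
of the night — rather than saturating. The insect-band amplitude
modulation uses stridulation-scale pulse rates (80–200 Hz), so the buzz
is quasi-stationary at the 60 ms gain-control timescale. What passing
tests on this generator show is that the implementation reproduces the
*mechanisms* (masking by decaying noise, per-sensor calibration drift);
they do not certify field accuracy on real soundscapes, which contain
confounders (sirens, speech, rain) the generator does not model.

## Scaled-down study design

The bundled experiments run on desk-scale problem sizes, chosen once:

* `robustness_experiment()`: five seeded replicates; 75 s nights, four
  sensors (two train, two test), event rate 8→32 events/min, 24 + 24
  clips per training sensor, the small model (8/8/16 kernels, 32 hidden
  units), 16 epochs, context window 37.5 s sampled every 9.375 s,
  recall in 37.5 s segments. Each model operates at its own best-F1
  threshold calibrated on training sensors only. Reported: early-segment
  recall of the log-mel vs PCEN baselines on held-out sensors, and the
  across-sensor IQR of overall recall for the PCEN baseline vs the AT
  model.
* `gaussianization_experiment()`: five 30 s background-only nights;
  skewness of standardized log-mel vs PCEN(outdoor) magnitudes.
* `decay_recovery_experiment()`: one 120 s background-only night with a
  programmed 10 dB decay, recovered from the 2–2.5 kHz SPL trend in 12
  segments.

The full-scale protocol (ten-hour nights, six sensors, 70k clips,
hundreds of training runs) is out of reach by design; the desk-scale
experiments preserve its structure — leave-sensor-out splits, the decay
and rate ramps, per-model operating points — at roughly four orders of
magnitude less compute.

## Numerical choices and degenerate inputs

* Log floor `1e-10` keeps silent bins finite in `logmelspec()`.
* PCEN of exact silence is exactly zero.
* `magnitude_distribution()` refuses constant matrices (zero variance).
* Quantile estimator: type 7 (linear interpolation), stated because
  nine-point summaries at permille levels are sensitive to the rule.
* The matcher treats ties between equal-cardinality matchings as
  irrelevant (metrics depend on cardinality only).
* WAV I/O supports PCM16 and float32, mono; stereo is averaged with a
  warning. Audio at other rates is resampled to 22,050 Hz.

## Known limitations

* No FLAC decoding; recordings must be WAV.
* Feature and model serialization uses R's native RDS format rather than
  a cross-language container.
* The trainer is CPU-bound and single-threaded; it is sized for the
  scaled-down experiments, not for 70k-clip datasets.
* Trainable, frequency-dependent PCEN parameters are out of scope.
* The AT+MoE hybrid is deliberately not provided.
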