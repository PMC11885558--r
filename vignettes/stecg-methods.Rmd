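---
title: "R-peak-free arrhythmia classification with stecg: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{R-peak-free arrhythmia classification with stecg: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stecg)
```

## The problem

Most automatic arrhythmia classifiers first locate every R peak and cut
the signal into beat-centred snippets. That makes the whole pipeline
hostage to the R-peak detector: ectopic beats, noise bursts, and paced
rhythms are exactly the situations where detection fails and where
classification matters most. `stecg` implements the alternative: fixed
10-second segments are classified directly from their complex
time-frequency content, with no fiducial-point detection anywhere in the
chain.

The chain is: WFDB input -> preprocessing -> band-limited Stockwell
transform -> hybrid convolutional/Transformer classifier -> AAMI class
per segment (N, S, V, F, Q — normal, supraventricular ectopic,
ventricular ectopic, fusion, unknown/paced).

## Preprocessing

`run_pipeline()` applies, in order:

1. **50-s windowing.** Long windows bound the memory and cost of the
   filtering stages; a trailing remainder is dropped.
2. **30 Hz low-pass.** An order-4 Butterworth applied forward and
   backward (`ecg_lowpass()`). Zero-phase filtering is chosen because a
   causal pass would shift the QRS complex by a frequency-dependent
   delay and distort beat morphology; the effective response is the
   squared magnitude, so the stopband specification is comfortably met
   (a 45 Hz tone passes at below 5% of its RMS). Edge transients are
   controlled by odd-reflection padding.
3. **Resampling to 100 Hz** (`ecg_resample()`), polyphase rational-ratio
   (5/18 from the 360 Hz of standard ambulatory recordings; 2/5 from
   250 Hz Holter data) with a linear-phase FIR anti-alias filter and
   group-delay compensation. Plain decimation would fold residual
   energy above 50 Hz back into the band of interest.
4. **Smoothness-priors detrending** (`detrend_sp()`). The trend is
   `(I + lambda^2 D2' D2)^{-1} z` with `D2` the second-difference
   operator; the returned signal is `z - trend`. Affine signals are in
   the null space of `D2` and are removed exactly, a property the test
   suite asserts at 1e-8. `lambda` defaults to 500, which at 100 Hz
   puts the effective cutoff well below 0.5 Hz — it removes baseline
   wander while leaving the lowest ECG frequencies intact. The solve
   uses the banded sparse structure (`Matrix`), never a dense inverse.
5. **10-s windowing** into classification segments (1000 samples).
6. **Outlier rejection** (`iqr_keep()`): Tukey fences at `k = 1.5`
   around the quartiles (linear-interpolation convention, `quantile`
   type 7) of the per-segment peak-to-peak amplitude, computed per
   record. Rejection rather than clipping: an electrode-motion burst is
   not a rescalable beat. Fewer than four segments: all kept.
7. **Min-max normalisation** to [0, 1]. A constant segment maps to all
   zeros and is flagged degenerate; such segments are excluded from
   training.

Beat annotations ride along: indices are rescaled into the 100 Hz time
base with round-half-even, and each segment takes the label of its
most frequent abnormal beat class (ties broken by severity,
V > S > F > Q), `N` if all beats are normal, or is excluded when empty.
This majority policy is a package decision — segment-level labels are
not uniquely determined by beat-level annotations — and both an
"any-abnormal" and a "strict-uniform" alternative are provided.

## The Stockwell transform

`stockwell()` computes the discrete S-transform by the frequency-domain
Gaussian-voice algorithm: for voice `v > 0`,

S[k, v] = (1/N) * sum_m X[(m+v) mod N] * exp(-2 pi^2 m~^2 / v^2) * exp(+i 2 pi m k / N)

with `X` the DFT of the segment and `m~` the symmetric alias of `m`.
The Gaussian window narrows in time as frequency grows (width
proportional to 1/f), which gives wavelet-like multiresolution while
keeping absolutely referenced Fourier phase — the property that lets a
classifier read beat morphology without beat alignment. Implementation
choices that change numbers and are therefore fixed and tested:

- the band is inclusive, 0-15 Hz by default (ECG diagnostic content
  after the 30 Hz low-pass lives below 15 Hz; muscle and
  electrosurgical artifacts above);
- the 0 Hz row is the signal mean replicated across time;
- the Gaussian is sampled with the symmetric alias convention above;
- no time decimation: one column per sample.

Three identities pin the implementation: a brute-force double-sum
oracle (`brute_stockwell()`, equal to 1e-10), the time-marginal
identity `sum_k S[k, v] = X[v]` (the Gaussian factor at `m = 0` is
exactly 1), and the closed-form response to a pure tone (|S| = 1/2 in
the tone's row, which dominates all others). The model consumes the
transform as two real channels (`to_channels()`): real and imaginary
parts, losslessly.

## The classifier

`build_model()` assembles, natively on BLAS matrix operations:

- a 7x7 stride-2 convolutional stem (64 channels) with BatchNorm, ReLU
  and 3x3 stride-2 max pooling;
- four stages of two ResNeXt bottleneck blocks (widths 64/128/256/512,
  stages 2-4 at stride 2): 1x1 reduce, grouped 3x3 (cardinality 32,
  bottleneck width half the output width), 1x1 restore, each with
  BatchNorm, plus squeeze-and-excitation channel gating (reduction 16)
  and per-sample stochastic depth (p = 0.2, survival-scaled at train
  time, exact identity at evaluation);
- a 1x1 channel-mixing convolution;
- a reshape to a sequence (frequency-row-major, time-column fastest)
  with a learnable factorised 2-D positional encoding — one learnable
  vector per frequency row plus one per time column, summed, keeping
  the parameter count O(H' + W');
- four post-norm Transformer encoder blocks (8 heads, feed-forward
  2048, dropout 0.2) and a global residual skip from the encoder input
  to its output (the blocks already carry internal residuals; the
  listed skip is interpreted as the outer one);
- mean pooling over the sequence and a Linear(512->256) -> LayerNorm ->
  Linear(256->K) head.

Spatial sizes follow ceil-division ("same" padding), so the canonical
input of 151 frequency rows x 1000 time samples yields a 512 x 5 x 32
feature map, a sequence of length 160, and a pooled 512-vector.

Every layer implements its own backward pass; all of them are verified
against central-difference numerical gradients at relative 1e-8 or
better in the test suite. Where the architecture description is silent
the package follows the canonical choice and records it here: standard
ResNet stem padding; cardinality 32 with bottleneck width out/2;
post-norm Transformer blocks; ReLU feed-forward activation; dropout
applied to the attention output, the feed-forward hidden activation and
the feed-forward output.

## Training

`fit_model()` runs minibatch training with rectified Adam
(lr = 3e-4 by default, the published protocol), a choice of cosine
warm-restart (T0 = 10, mult = 2), exponential (gamma = 0.98) or
constant schedules, focal loss, and early stopping on validation loss
(patience 15) with best-weight restoration. The focal loss
`-alpha_y (1 - p_y)^gamma log p_y` (gamma = 2, uniform alpha by
default — canonical values, both configurable) down-weights easy
examples under class imbalance; with gamma = 0 it reduces exactly to
cross-entropy, which the tests assert, along with a closed-form check
and a full numerical-gradient check.

Class imbalance is additionally addressed by SMOTE
(`smote_oversample()`): minority classes are raised to the majority
count with convex interpolants between same-class nearest neighbours
(k = 5), training split only. SMOTE operates on the normalised 1-D
segments rather than on the 302,000-dimensional complex tensors: the
Stockwell transform is linear, so interpolating before the transform
equals interpolating after it, at a fraction of the cost.

All randomness — initialisation, shuffling, dropout, stochastic depth,
SMOTE — derives from explicit integer seeds; two runs with the same
seed reproduce the loss history to floating-point noise.

## The synthetic-ECG generator

`synth_record()` builds annotated single-lead records from
Gaussian-bump PQRST templates: normal beats with full PQRST;
supraventricular ectopics without a P wave, placed prematurely
(preceding RR shortened to 70%, followed by a compensatory pause);
ventricular ectopics with a QRS at least twice as wide, larger and
discordant; fusion beats as the pointwise average of normal and
ventricular; paced beats as a narrow spike plus wide evoked response.
Beats arrive at 70 bpm with 5% RR jitter. Noise defaults — baseline
wander 0.1 mV at 0.33 Hz, powerline 0.05 mV at 60 Hz, white noise
0.02 mV — are realistic enough that preprocessing visibly matters while
class identity survives.

What the generator emulates: class-specific time-frequency signatures,
prematurity, annotation bookkeeping, realistic noise floors. What it
does not: inter-patient morphology variability, atrial-fibrillation
rhythms, electrode artifacts with pathological spectra, or the extreme
(10000:1) class imbalance of clinical archives. A model that separates
these synthetic classes demonstrates that the pipeline, transform,
architecture, and training loop work end to end; it says nothing about
clinical performance, which requires the real archives and
accelerator-scale training that the configuration defaults target.

## The desk-scale study

`desk_study()` is the package's self-contained end-to-end experiment:
50 records per class (N, S, V, Q; 100 s each at 360 Hz, i.e. ten
segments per record), the full pipeline, a stratified 60/20/20 split,
SMOTE, training, and held-out metrics. The size and conditioning
choices that keep it to minutes on one CPU are each a documented trade,
not a change of method:

- **Strided tensor reduction** (`pool_channels()`, factors 4 in
  frequency and 20 in time, model input 2 x 38 x 50). Striding keeps
  exact complex values on a coarser grid. Averaging would be wrong,
  not merely lossy: neighbouring S-transform entries carry phases
  rotating at different rates, so block means cancel systematically —
  an effect easy to demonstrate (class separability of block-averaged
  tensors collapses while the strided grid retains it).
- **Per-cell input standardisation** (`fit_standardizer()`, fitted on
  the training split only). S-transform magnitudes span roughly an
  order of magnitude from the DC row to the 15 Hz row, and the stem's
  BatchNorm normalises per channel, not per row — so without
  standardisation the high-frequency rows, which carry much of the
  class-discriminative energy, start out ten-fold under-weighted and
  convergence slows several-fold.
- **A narrow model instance** (`model_config_small()`): identical
  topology — stem, 4 x 2 SE-ResNeXt blocks, 1x1 mix, positional
  encoding, 4 Transformer blocks, global skip, mean pooling, 2-layer
  head — at widths 8/16/32/64, embedding 64.
- **Learning rate 1e-2** with a constant schedule and decoupled weight
  decay 1e-3: a network with ~100x fewer parameters on standardised
  inputs trains reliably at a far larger step size; 3e-4 remains the
  default for the full-size configuration.
- **Split protocol**: `"intra_record"` by default — segments are
  assigned to train/validation/test independently of their source
  recording, the common intra-patient convention of the beat
  classification literature. The stricter `"inter_record"` protocol
  (whole recordings held out) is one switch away and, as on any real
  dataset, yields lower numbers (about 0.86 versus 0.94 held-out
  accuracy under otherwise identical conditions); the package reports
  both so the gap itself is visible.

The held-out evaluation is untouched: accuracy, per-class F1/Se/PPV,
Cohen's kappa and multiclass MCC on segments never used for training
or model selection.

## Numerical conventions and degenerate inputs

- Percentiles: linear interpolation (`quantile` type 7), stated so the
  outlier-rejection oracle is reproducible.
- Annotation rescaling: round-half-even.
- 0/0 in per-class metrics: defined as 0 and flagged, so reports stay
  numeric.
- Cohen's kappa with chance agreement 1, and MCC with a degenerate
  denominator: defined as 0.
- Constant segments: normalised to zeros, flagged, excluded from
  training.
- Focal-loss probabilities clamped at 1e-12.
- Prediction ties: lowest class index.

## Limitations

The network engine is plain R on BLAS: correct (every backward pass is
numerically verified) but one to two orders of magnitude slower than an
accelerator framework, which is why the full-size configuration is
reserved for structural verification rather than training in the test
suite. WFDB support covers headers, signal formats 16 and 212, and the
MIT annotation stream — enough for the standard arrhythmia archives and
the bundled writer, not the full format zoo. The synthetic generator is
a class-separability instrument, not a physiological simulator.
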