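# stecg

R-peak-free arrhythmia classification from single-lead ECG: a complete,
self-contained R implementation of a Stockwell-transform + hybrid
ResNeXt-SE/Transformer pipeline.

## The problem

Beat-level arrhythmia classifiers conventionally segment the ECG around
detected R peaks, which couples classification quality to the weakest
link — the peak detector — precisely on the ectopic, paced and noisy
rhythms that matter. `stecg` classifies fixed 10-second segments
directly from their complex time-frequency content instead, assigning
each segment one AAMI class: **N** (normal), **S** (supraventricular
ectopic), **V** (ventricular ectopic), **F** (fusion), **Q**
(unknown/paced).

## The method

For a segment *x* of length *N* at 100 Hz, the discrete Stockwell
transform is computed per frequency voice *v* by the Gaussian-voice
algorithm

> S[k, v] = (1/N) Σₘ X[(m+v) mod N] · exp(−2π² m̃²/v²) · exp(+i2πmk/N)

with X the DFT of *x* and m̃ the symmetric alias of *m* — a
time-frequency representation with frequency-dependent resolution
(window width ∝ 1/f) and absolutely referenced phase. The band is
restricted to 0–15 Hz (151 rows at N = 1000) and split into real and
imaginary channels.

A hybrid network consumes the 2×151×1000 tensor: a ResNeXt feature
extractor (7×7/2 stem + max-pool; four stages of two grouped-convolution
bottleneck blocks with squeeze-and-excitation gating and stochastic
depth; widths 64→512), a 1×1 mixing convolution, a learnable 2-D
positional encoding over the 5×32 feature grid, four Transformer
encoder blocks (8 heads, FFN 2048, dropout 0.2) under a global residual
skip, mean pooling, and a two-layer classification head. Training uses
rectified Adam (3e-4), focal loss (γ = 2), SMOTE oversampling of the
training split, cosine warm-restart or exponential schedules, and early
stopping (patience 15).

Everything — the preprocessing pipeline (zero-phase 30 Hz Butterworth,
polyphase resampling to 100 Hz, smoothness-priors detrending
(I + λ²D₂ᵀD₂)⁻¹, IQR outlier rejection, min-max normalisation), the
transform, the network with its hand-derived backward passes, the
optimiser, WFDB input/output, and an annotated synthetic-ECG
generator — is implemented in this package on base R + BLAS; no deep
learning framework is required.

## Worked example

```r
library(stecg)

# a synthetic annotated record: 60 s, mostly normal with ventricular ectopics
rec <- synth_record(synth_config(duration_s = 60,
                                 class_mix = c(N = 0.65, V = 0.35),
                                 seed = 7))
rec
#> <raw_record syn00007> 21600 samples @ 360 Hz (60.0 s), lead synthMLI, 69 annotations

# preprocessing: windows, filter, resample, detrend, reject, normalise, label
segs <- run_pipeline(rec, preprocess_config(), class_scheme("icentia"))
dplyr::count(segs, label, kept)
#> # A tibble: 1 × 3
#>   label kept      n
#>   <chr> <lgl> <int>
#> 1 V     TRUE      5

# the time-frequency representation of one segment
s <- stockwell(segs$samples[[1]], fs = 100)
s
#> <st_matrix> 151 frequency rows (0.00-15.00 Hz) x 1000 time samples @ 100 Hz
autoplot(s)   # spectrogram-style magnitude plot

# classify with the hybrid model (untrained weights here, for shape only)
model <- build_model(model_config(n_classes = 4), seed = 1)
logits <- model_forward(model, to_channels(s))
dim(logits)
#> [1] 4 1
```

Each row of `segs` is one 10-second segment: its source record, start
time, majority-abnormal beat label (`V` above — every window contains
ventricular ectopics), whether it survived outlier rejection, and the
normalised samples. The S-transform matrix has one 0.1 Hz-spaced row
per retained frequency and one column per sample; `to_channels()`
yields the 2-channel tensor the network consumes, and the logits are
one unnormalised score per class.

The full end-to-end experiment — simulate records for four classes,
preprocess, transform, train the (narrow) hybrid model, evaluate on
held-out records — is one call:

```r
res <- desk_study(n_per_class = 50, seed = 1)
glance(res$report)      # held-out accuracy, macro F1, kappa, MCC
autoplot(res$report)    # confusion heat map
autoplot(res$history)   # loss curves
```

## Scope

The package trains and evaluates at desk scale on its synthetic
generator out of the box. The same functions accept real WFDB records
(`read_record()` supports signal formats 16 and 212 and MIT-format
annotations), but reproducing archive-scale published accuracies
requires the archives themselves and accelerator-scale compute, which
are outside what this package bundles.
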