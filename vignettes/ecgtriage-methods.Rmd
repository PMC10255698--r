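---
title: "Methods: the beat classifier, its preprocessing chain, and the vitals triage rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the beat classifier, its preprocessing chain, and the vitals triage rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`ecgtriage` implements the computational half of a home remote-monitoring
workflow: classify single ECG beats into the five-class arrhythmia scheme
(normal, supraventricular premature, premature ventricular contraction,
fusion, unclassifiable) with an attention-augmented 1D convolutional
network, and screen vitals telemetry (body temperature, heart rate, SpO2)
with transparent threshold rules. Sensor hardware, live MQTT transport and
any clinical claim are out of scope; telemetry is handled only as stored
topic/JSON messages.

## The classifier

The network consumes one z-normalized beat of 186 samples. Its layer
sequence is fixed; widths are configurable through `model_config()`:

```
conv(64, k=5, ReLU) -> BN -> maxpool(2)
conv(128, k=5, ReLU) -> BN -> maxpool(2)
conv(256, k=5, ReLU) -> BN -> maxpool(2)
attention -> flatten
dense(512, ReLU) -> BN -> dropout(0.5)
dense(256, ReLU) -> BN -> dropout(0.5)
dense(5) -> softmax
```

Convolutions use "same" padding so the time axis shrinks only at the
pooling steps (186 -> 93 -> 46 -> 23). For input `x`, filter weights `W`
and bias `b`, a convolutional layer computes `y = f(x * W + b)` with
`f = ReLU`; batch normalization standardizes each channel with batch mean
and population variance plus learned scale `gamma` and shift `beta`
(`eps = 1e-5`, running statistics with momentum 0.1 serve inference); max
pooling takes non-overlapping windowed maxima (window 2, trailing
remainder dropped, ties to the earliest position).

The attention layer scores each timestep of the final 23 x 256 feature
map, `q_t = tanh(x_t . W_att + b_att)`, converts scores to weights with a
softmax over timesteps (`a_t >= 0`, `sum_t a_t = 1`), and rescales the
map elementwise, `attended_t = a_t * x_t`. Two readings of this operator
are possible — elementwise rescaling or pooling to a single context
vector; the layer definition here multiplies and keeps the
time-by-channel shape, and the attended map is then flattened into the
dense head. Dropout is the inverted variant: units are kept with
probability `1 - p` and scaled by `1/(1 - p)` during training, so
inference is exactly the identity.

Training minimizes categorical cross-entropy with Adam
(`beta1 = 0.9`, `beta2 = 0.999`). The defaults — filters 64/128/256,
kernel 5, dense 512/256, dropout 0.5, learning rate 0.001, batch size
512, 25 epochs — are the grid-selected operating point of the reference
architecture. The optimizer and loss are standard choices recorded here
as package decisions. Every stochastic element (initialization, epoch
shuffling, dropout masks) derives from the configuration seed through a
local RNG, so runs are bit-reproducible and no global random state is
touched. Layer output counts differ across published descriptions of
this architecture family (a six-layer narration with two conv blocks
versus a detailed three-conv-block account); this package implements the
three-block account, which matches the selected filter triple 64/128/256.

The whole network — forward passes, backward passes, Adam — is written in
R on top of BLAS matrix multiplication (convolution via im2col). The
backward pass is verified in development against central finite
differences; the test suite checks each layer against independent
brute-force oracles (windowed maxima, constant-batch batch-norm, binomial
dropout counts, a hand-evaluated two-timestep attention example).

## Preprocessing chain

Raw traces (e.g. 10 s at 250 Hz, 2500 samples) pass through:

1. **Bandpass 0.5-100 Hz** — order-4 Butterworth applied
   forward-backward (`signal::filtfilt`), zero phase so beat morphology
   is not skewed. The realization is a package decision; the band is the
   chain's defining parameter.
2. **Resampling to 125 Hz** — polyphase (`signal::resample`), output
   trimmed/padded to exactly `round(n * fs_out / fs)` samples.
3. **Per-beat z-normalization** — subtract the mean, divide by the
   population (divide-by-N) standard deviation; the divisor is a package
   decision. Constant windows map to zeros with a warning.
4. **Segmentation** — candidate R-peaks are local maxima above an
   adaptive threshold (midway between trace mean and maximum) separated
   by at least 0.3 s; a 186-sample window centered on each peak is
   extracted, zero-padded at trace edges. This is a phantom-signal
   detector, not a validated QRS algorithm. Native units are arbitrary:
   normalization makes the classifier input dimensionless, so ADC
   gain/resolution of the acquiring front end is irrelevant.

The 186-sample window matches the classifier input; the public heartbeat
CSV corpus ships 187 value columns, and `read_beat_csv()` bridges the two
by dropping the final column, loudly.

## Synthetic data: what it emulates and what it does not

`generate_beat()` builds a beat as a sum of Gaussian bumps — the P, Q, R,
S, T deflections — on a flat baseline, with per-wave timing jitter, white
noise, and a low-frequency sinusoidal baseline wander. Class defaults
(package constants, synthetic conventions rather than physiological
claims):

* class 0: textbook morphology, upright narrow R;
* class 1: attenuated P (amplitude 0.02 vs 0.15) and early timing
  (centers shifted 0.07 of the window);
* class 2: no P, widened (width 0.055 vs 0.018) inverted R with
  discordant T;
* class 3: the half-amplitude superposition of the class-0 and class-2
  waveforms — a parameter-wise average of the five canonical waves would
  cancel the opposite-polarity R and T almost exactly and collapse the
  class into noise, whereas a fusion beat is physically the superposition
  of two activation fronts, so the morphology container admits any
  number of Gaussian components;
* class 4: a single broad low bump with noise SD 0.30 and jitter SD 0.05.

Jitter/noise/wander defaults (0.008 / 0.04 / 0.05 in beat-window and
amplitude units) were fixed once at values that leave the classes clearly
distinguishable yet non-trivial; a nearest-centroid baseline on a fresh
draw must exceed 0.8 accuracy, and this calibration is itself a test. The
generator does **not** emulate inter-patient variability, electrode
artefacts, class imbalance, or the overlapping morphology continua of
real arrhythmia data — passing tests demonstrate that the implementation
learns separable morphology classes, not that it reaches any particular
accuracy on clinical recordings. Running the pipeline on the public
heartbeat corpus at the default hyperparameters is the corresponding
external check; it needs a download and GPU-scale time, so it is
documented rather than tested.

Vitals streams are baselines plus Gaussian jitter with additive scripted
episodes (fever, tachycardia, bradycardia, desaturation) over index
ranges; SpO2 is capped at 100%.

## Evaluation

`confusion_matrix()` counts true-by-predicted pairs; `metrics_report()`
derives accuracy (trace over total), per-class precision `TP/(TP+FP)`,
recall `TP/(TP+FN)`, F1 (harmonic mean), supports, and macro
(unweighted) and support-weighted averages. Zero-denominator classes
report 0 with a warning — a convention, stated rather than silent.
`grid_search()` enumerates the full cartesian grid, scores validation
accuracy (a divergent run scores 0), breaks ties by grid order, and
supports a reduced epoch budget per point so searches stay desk-scale;
the winning configuration keeps its own epoch count for final
retraining. The split policy is stratified 80/10/10; pre-split external
files are respected when supplied.

## Triage rules

* Temperature: fever at or above 100.4 °F. The boundary itself
  classifies as fever — the >= convention matches the clinical definition
  the threshold comes from. Readings outside 80-115 °F flag "invalid".
* Heart rate: age-banded inclusive ranges. Newborns (0-1 month) 70-190
  bpm, infants (1-11 months) 80-160 bpm, and everyone from 10 years up
  60-100 bpm are reference ranges; the child bands between (1-2 y
  80-130, 3-5 y 80-120, 6-9 y 70-110) are package defaults tagged
  `default-extrapolated` and overridable. An age not covered by exactly
  one band is an explicit error, never a silent fallback.
* SpO2: 95-100% normal, below 95% low; outside 0-100% is physically
  impossible for percent saturation and flags as sensor error.
  ("Excessively high oxygen" is unreachable on this scale.)
* Decision: alarm iff any reading shows fever, out-of-band heart rate or
  low SpO2, or the fraction of non-normal predicted beats exceeds a
  threshold (default 0.2, configurable). Beat-to-patient aggregation by
  fraction threshold is a package decision — no standard aggregation rule
  exists for this pipeline — and every triggered condition is listed in
  `reasons`, so the alarm bit is auditable and monotone in its inputs.

## Numerical choices and degenerate inputs

* Argmax ties in prediction break to the lowest class index.
* Softmax and cross-entropy are computed with max-subtraction and a
  `1e-12` probability floor.
* Non-finite gradients (a divergent learning rate) are zeroed for the
  Adam update so a grid search survives divergent corners.
* Constant beats normalize to zeros with a warning; flat traces segment
  to an empty list; empty triage input is an error.

## Problem sizes

The development-scale study conditions are 200 beats per class (1000
beats, 186 samples each), 25 epochs at batch 512 for the end-to-end
check, and a 50-beat subset at 200 epochs for the memorization check;
grid-search tests use reduced widths (4/6/8 filters) and epoch budgets.
These sizes exercise every code path at full architectural width while
keeping a complete run on one CPU core in minutes.
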