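# ecgtriage

Offline analysis stack for home remote-health monitoring: five-class ECG
heartbeat classification with an attention-augmented 1D convolutional
network, the standard ECG preprocessing chain, and a rule-based triage
engine for vitals telemetry (body temperature, age-banded heart rate,
SpO2). It is aimed at engineers and researchers prototyping
telemetry-to-decision pipelines who need every stage — signal
conditioning, classifier, metrics, alarm rules — testable on one machine
without sensor hardware or a data download: a synthetic generator
produces labelled beats with five distinguishable morphologies and vitals
streams with scripted abnormal episodes.

## The model

A beat is a z-normalized 186-sample window centered on the R peak. The
classifier is

```
conv(64, k=5, ReLU) → BN → maxpool(2)
conv(128, k=5, ReLU) → BN → maxpool(2)
conv(256, k=5, ReLU) → BN → maxpool(2)
attention → flatten
dense(512, ReLU) → BN → dropout(0.5)
dense(256, ReLU) → BN → dropout(0.5)
dense(5) → softmax
```

where the attention layer scores each timestep of the final feature map,
`q_t = tanh(x_t·W + b)`, forms weights `a = softmax_t(q)`, and rescales
the map elementwise, `attended_t = a_t · x_t`. Training is Adam on
categorical cross-entropy (lr 0.001, batch 512, 25 epochs by default).
The network, its backpropagation and the optimizer are implemented from
first principles in R on BLAS matrix operations; no deep-learning
framework is required. Evaluation reports the multiclass confusion
matrix with per-class/macro/weighted precision, recall and F1. Triage
applies transparent thresholds — fever at ≥ 100.4 °F, age-banded heart
rate (e.g. newborn 70–190 bpm, adult 60–100 bpm), SpO2 normal at 95–100%
— and raises an alarm iff any rule fires or the fraction of non-normal
beats exceeds a configurable threshold, listing every reason.

## Worked example

```r
library(ecgtriage)

ds  <- generate_dataset(200, length = 186, seed = 5)   # 1000 beats, 5 classes
ds  <- assign_splits(ds, seed = 5)                     # stratified 80/10/10
cfg <- model_config(seed = 1)                          # the default architecture
fit <- train_model(build_model(cfg), ds, cfg)

held <- which(ds$split %in% c("val", "test"))
pred <- predict(fit, ds$beats[held, ])$label
metrics_report(confusion_matrix(ds$labels[held], pred, 5))
#> Evaluation over 200 beats; accuracy 1.0000
#>  class precision recall f1 support
#>      0         1      1  1      40
#>      1         1      1  1      40
#>      2         1      1  1      40
#>      3         1      1  1      40
#>      4         1      1  1      40
#> macro    P 1.0000  R 1.0000  F1 1.0000
#> weighted P 1.0000  R 1.0000  F1 1.0000
```

On the synthetic study conditions the default network separates the five
morphology classes perfectly within a few epochs — the classes are
constructed to be learnable (a nearest-centroid baseline already exceeds
0.8), so this validates the implementation, not clinical performance.

Triage on a vitals stream with a scripted fever episode:

```r
p <- vitals_profile(episodes = list(vitals_episode(10, 20, "temp_f", 3.0)))
s <- generate_vitals_stream(p, 30, seed = 2)
triage(s, beat_labels = rep(0L, 20))
#> Triage: ALARM
#>   - fever: 11 reading(s) at or above 100.4 F (max 101.8 F)
#> beat class histogram (0..4): 20 0 0 0 0
```

A command-line surface over the same functions (subcommands `simulate`,
`preprocess`, `train`, `evaluate`, `predict`, `triage`, `gridsearch`)
ships at `inst/cli/ecgtriage.R`.

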