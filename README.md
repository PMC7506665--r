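# avfbruit

Objective scoring of arteriovenous fistula (AVF) bruit from auscultation
audio, for the dialysis teams and biomedical-signal researchers who
monitor vascular access by ear today.

The bruit — the audible turbulence of blood flowing through the
artery-to-vein access — changes as the vessel stenoses. `avfbruit`
re-implements, as a tested R package, a deep-learning auscultation
pipeline that turns a one-minute bedside recording into per-heartbeat
class probabilities over the five clinically recognised sound types
(*normal*, *hard*, *high*, *intermittent*, *whistle*) and explains each
decision with a Grad-CAM heatmap:

1. **Single-beat extraction.** The recording is reduced to a 2–750 Hz
   short-time energy envelope `E(t)` (mean in-band magnitude per 50 ms
   frame), smoothed with a cubic spline, and cut into convex
   minimum-to-minimum ranges of 0.5–2 s — one heartbeat each. A binary
   CNN gate keeps a candidate only if
   `P(AVF | log-mel spectrogram) > 0.5`.
2. **Log-mel features.** STFT (window 4096, hop 2048, at 192 kHz), mel
   filter bank capped at 2000 Hz, `log(M·S + 1e-10)`, per-clip
   standardisation, blank-padding to a fixed 400-frame time axis.
3. **Classifiers.** VGG13-style CNN and CRNN (Bi-GRU / Bi-LSTM)
   networks — pairs of 3×3 convolutions with batch norm and ReLU, 2×2
   max pools taking 400 time frames to exactly 12 at the recurrent
   input, softmax over 5 classes — trained with inverse-frequency class
   weights `w_c = N/(K·N_c)` under Adam. The engine (forward and
   backward) is written in RcppArmadillo; no external deep-learning
   framework is required.
4. **Selection, stacking, reporting.** Per-class one-vs-rest ROC/AUC,
   per-class best-model selection, a logistic stacking meta-classifier,
   Table-style metric reports (accuracy, precision, recall,
   specificity, F1, AUC) and longitudinal class-proportion trends.
5. **Interpretation.** Grad-CAM over the convolutional trunk localises
   the time–frequency evidence for any class.

No patient audio is distributed; a seedable synthetic bruit generator
(class-specific acoustic signatures, variable heart rate, environmental
hum/babble/clatter, archive-like class imbalance, simulated patients
with grouped train/test splits) makes every stage testable end to end.

## Worked example

Simulate a labelled corpus, train a small CRNN, and score held-out
beats from patients the model never saw:

```r
library(avfbruit)

corpus <- synth_corpus(
  n_per_class = c(normal = 12, hard = 12, high = 12,
                  intermittent = 12, whistle = 12),
  seed = 42
)
cf <- corpus_features(corpus, n_mels = 64)

model <- build_model(
  architecture_spec("crnn_bigru", n_mels = 64, base_channels = 4),
  seed = 7
)
tr <- cf$split == "train"
model <- train_model(model, cf$features[tr], cf$labels[tr],
                     cf$patient_id[tr],
                     training_config(epochs = 6, seed = 7))

pred <- predict(model, cf$features[!tr])
report <- metrics_report(pred, cf$labels[!tr])
print(as.data.frame(report), digits = 3)
```

```
         class accuracy precision recall specificity    f1 auc
1       normal     1.00       1.0    1.0       1.000 1.000   1
2         hard     0.90       1.0    0.5       1.000 0.667   1
3         high     1.00       1.0    1.0       1.000 1.000   1
4 intermittent     1.00       1.0    1.0       1.000 1.000   1
5      whistle     0.90       0.5    1.0       0.889 0.667   1
6        macro     0.96       0.9    0.9       0.978 0.867   1
```

Each row is a one-vs-rest confusion for that class on the held-out
beats (here 20 beats from 3 unseen simulated patients): every class's
probability ranking is perfect (AUC 1), one `hard` beat is argmax-ed as
`whistle`, which costs hard's recall and whistle's precision, and the
`macro` row averages the five classes. At this miniature scale the
numbers move with the seed; the acceptance script below runs the
larger, fixed study conditions.

To see *why* a beat is called `high`, compute its heatmap — the heat
concentrates in the systolic 250–750 Hz region:

```r
beat <- featurize_beat(synth_beat(beat_spec("high", seed = 1)))
cam <- grad_cam(model, beat, "high")
dim(cam$values)   # 400 x 64, the input grid, values in [0, 1]
```

A thin command-line surface wraps the same functions:

```sh
Rscript inst/cli/avfbruit.R simulate --n-per-class 10 --seed 7 --out corpus/
Rscript inst/cli/avfbruit.R segment --wav recording.wav --out beats/
```

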