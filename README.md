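# drowsEEG

Drowsy driving is a major cause of road fatalities, and the transition from
alert wakefulness to drowsiness leaves a clear spectral signature in scalp
EEG: power shifts from the beta band (14–25 Hz) into alpha (8–14 Hz) and the
slow-wave theta (4–8 Hz) and delta (0.5–4 Hz) bands. **drowsEEG** is an R
package for neurophysiology and BCI researchers that implements a complete
passive brain–computer-interface pipeline around that signature:

* **Preprocessing** — 50/60 Hz notches, breathing-band rejection and a
  3rd-order Butterworth low-pass retaining 0.5–40 Hz, applied zero-phase
  (`preprocess_recording()`, `frequency_response()`).
* **Spectral estimation** — Welch PSD (Hamming taper, 50% overlap, density
  convention) and Gaussian-tapered spectrograms (`welch_psd()`,
  `spectrogram()`, `band_power()`).
* **Features** — per 10-s window and channel, the four band powers
  P̄_δ, P̄_θ, P̄_α, P̄_β and the four band-power ratios
  R1 = (α+θ)/β, R2 = α/β, R3 = (α+θ)/(α+β), R4 = θ/β, plus min–max
  rescaling to [0, 1] (`extract_features()`, `rescale_features()`).
* **Feature-ranking ensemble** — MRMR, chi-square and ReliefF rankings
  fused by Z-score into a global predictor importance,
  GPI = (1/3) Σᵢ (xᵢ − μᵢ)/σᵢ (`rank_features()`, `gpi_rank()`).
* **Classification** — 22 presets over seven families (trees, discriminant
  analysis, logistic regression, naive Bayes, Gaussian SVMs with kernel
  scales √P/4, √P, 4√P, six kNN variants, five ensembles) under stratified
  10-fold cross-validation, exhaustive 2–5-feature combination search, and
  seeded ensemble tuning (`cross_validate()`,
  `exhaustive_feature_search()`, `tune_best()`).
* **Evaluation and channel selection** — confusion-matrix metrics
  (accuracy, precision, recall, F1, specificity, MCC, Cohen's κ, fall-out),
  ROC/AUC, two-way replicated ANOVA, and channel-of-interest selection via
  Bonferroni-corrected paired t-tests (`compute_metrics()`, `roc_auc()`,
  `select_coi()`).
* **Synthetic sessions** — a seedable generator of labelled alert/drowsy
  multichannel recordings with realistic spectral structure, artifacts and
  subject variability (`generate_session()`), plus CSV/EDF input/output.

Everything is tidyverse-native: functions take a data frame (or a light
`eeg_recording` container) first and return tibbles, results have
`tidy()`/`glance()`/`autoplot()` methods, and calls chain with the pipe.

## Worked example

Generate one 10-minute synthetic session, preprocess it, extract the
windowed features, rank them on the F8 channel, and cross-validate the
bagged-tree ensemble:

```r
library(drowsEEG)
library(dplyr)

rec <- generate_session(session_config(duration_s = 600), seed = 42)
rec
#> <eeg_recording> subject S01: 6 channel(s) [Fp1, Fp2, F7, F8, O1, O2],
#>   600.0 s @ 125 Hz, 53.0% drowsy

feats <- rec |> preprocess_recording() |> extract_features() |> rescale_features()
f8 <- filter(feats, channel == "F8")

rank_features(f8)$gpi
#>   feature          gpi rank good_candidate
#> 1      r3  1.062535268    1          FALSE
#> 2 p_delta  0.881977055    2          FALSE
#> 3      r2  0.510465869    3          FALSE
#> 4      r1  0.485325198    4          FALSE
#> 5      r4 -0.009049848    5           TRUE
#> 6 p_alpha -0.727595657    6          FALSE
#> 7 p_theta -1.028521404    7          FALSE
#> 8  p_beta -1.175136481    8          FALSE

cv <- cross_validate(f8, "bagged_trees", seed = 7)
glance(cv)[, c("preset", "accuracy", "recall", "specificity", "mcc", "kappa", "auc")]
#>   preset       accuracy recall specificity   mcc kappa   auc
#> 1 bagged_trees     0.95      1       0.889 0.903 0.898 0.976
```

The GPI column is the mean Z-score of each feature across the three ranking
methods (zero mean by construction; the ±0.3 band marks "good candidate"
features). The `glance()` row holds the pooled out-of-fold confusion-matrix
metrics: here the ensemble classifies 95% of the 60 windows correctly, with
perfect sensitivity to drowsy windows and an AUC of 0.98 — a single short
session is an easy problem; multi-subject cohorts (see
`run_pipeline()` / `recovery_study()`) sit in the high-0.8s on the channel
of interest.

A thin command-line front end over the same functions is installed at
`inst/cli/drowseeg` (subcommands `simulate`, `preprocess`, `features`,
`select`, `classify`, `evaluate`).

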