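---
title: "Spectral-signature drowsiness detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-signature drowsiness detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

drowsEEG implements a passive brain–computer-interface pipeline that detects
driver drowsiness from multichannel EEG, together with a seedable synthetic
generator of labelled alert/drowsy sessions used to exercise the pipeline end
to end. This vignette explains the underlying models, the parameters that
matter, and the design decisions taken where the design was genuinely open.

## The detection problem

During the transition from alert wakefulness to drowsiness, scalp EEG power
shifts from the beta band (14–25 Hz) into alpha (8–14 Hz) and the slow-wave
theta (4–8 Hz) and delta (0.5–4 Hz) bands. The pipeline quantifies this shift
in 10-second windows and classifies each window as drowsy (label 1, the
positive class) or alert (label 0). Six channels of the 10–20 montage are
analysed — Fp1/Fp2 (prefrontal), F7/F8 (frontal), O1/O2 (occipital), sampled
at 125 Hz — and the pipeline additionally selects the single channel of
interest (COI) whose features classify best, validated by paired statistics.

## Preprocessing

`preprocess_recording()` applies, per channel and by default zero-phase
(forward–backward, preserving the alignment between labels and signal):

* a 3rd-order Butterworth high-pass at 0.5 Hz — this is also what removes
  sub-0.01 Hz drift (a dedicated 0.01 Hz stop band is numerically
  ill-conditioned at 125 Hz, and the retained band is identical);
* a second-order IIR notch centred on the 0.3–0.4 Hz breathing band
  (Q = 3.5, about 0.1 Hz wide);
* second-order IIR notches at 50 and 60 Hz (Q = 30). A notch is skipped with
  a warning when its frequency is within 2 Hz of Nyquist; at 125 Hz both are
  applied;
* a 3rd-order Butterworth low-pass at 40 Hz, so the retained band is
  0.5–40 Hz.

The application direction and the notch bandwidths are not physiological
constants; they are package choices, configurable through `filter_spec()`.
`frequency_response()` exposes the end-to-end magnitude response for
verification; the zero-phase mode squares each section's magnitude.

## Spectral estimation and features

`welch_psd()` averages Hamming-tapered, 50%-overlapping modified
periodograms in the one-sided density convention, so the rectangle-rule
integral of the PSD recovers the signal variance. The default segment length
is 2 s (250 samples at 125 Hz), giving 0.5 Hz resolution so that every band
edge (0.5, 4, 8, 14, 25, 40 Hz) falls on the frequency grid. Band powers are
rectangle-rule integrals over half-open intervals `[lo, hi)`, so shared band
edges are never double-counted. `spectrogram()` provides a Gaussian-tapered
short-time transform (width parameter 2.5, 10-s windows, 50% overlap) for
visual inspection of band dominance over time.

Each 10-s window yields eight features: the four mean band powers and the
four band-power ratios R1 = (α+θ)/β, R2 = α/β, R3 = (α+θ)/(α+β),
R4 = θ/β. R1 = R2 + R4 holds identically and is used as a self-check.
Ratios are computed on the raw band powers; min–max rescaling to [0, 1]
(`rescale_features()`) is applied afterwards to all eight features. A window
whose beta power is exactly zero gets flagged ratios (`NA`), never a silent
infinity. The window label is a duration-weighted majority vote over the
per-sample labels, with ties at exactly 50% going to the drowsy class.
Within cross-validation the min–max ranges are refitted on each fold's
training rows, so no information leaks from held-out windows; fitting on the
full table remains available for reproducing a single-pass analysis.

## Feature ranking and fusion

Three filter-type rankers are computed per channel on the pooled windows of
all subjects:

* **MRMR** — greedy forward selection on plug-in mutual information with
  10-cell equal-frequency discretization. The first pick maximizes relevance
  I(feature, label); each later pick maximizes the quotient of relevance to
  the mean mutual information with the already-selected set (an ε = 1e-12
  guards empty redundancy). Scores are the selection-time quotients.
* **Chi-square** — per feature, a 10-bin equal-frequency discretization, a
  bins × 2 contingency table, the χ² statistic with degrees of freedom
  reduced when bins are empty, and the importance score −log p. Features
  with p < 0.05 are marked significant.
* **ReliefF** — weights accumulated over all observations (k = 10 nearest
  hits and misses per class, Manhattan distance on range-normalized
  features, prior-probability weighting that reduces to 1 in the binary
  case). Random subsampling is used only if the caller requests fewer
  iterations than observations. The per-class neighbour count is read as
  "k per class", the reading consistent with the prior-weighted miss term.

`gpi_rank()` fuses the three score vectors by Z-scoring each across features
and averaging. The Z-score uses the sample (n−1) standard deviation — the
convention of common statistics software, and the one under which scores
{1, 2, 3} standardize to {−1, 0, 1}; the population convention is available
via `sd_type`. Features whose fused score lies within ±0.3 standard
deviations of zero are reported as "good candidates".

## Classification

Twenty-two presets over seven classifier families mirror a standard
preset catalogue: fine/medium/coarse trees (max splits 100/20/4), LDA/QDA,
logistic regression, Gaussian and kernel naive Bayes, fine/medium/coarse
Gaussian SVMs (kernel scales √P/4, √P, 4√P with box constraint C = 1 — for
P = 8 features these evaluate to 0.71, 2.8 and 11), six kNN variants
(1/10/100 neighbours, cosine and cubic distances, squared-inverse distance
weights), and five ensembles (bagged trees, AdaBoost and RUSBoost with 30
learners, learning rate 0.1 and 20 max splits, and random-subspace LDA/kNN
over 4-feature subspaces). Tree learners delegate to rpart; since rpart
bounds depth rather than split count, a max-splits budget s is mapped to
maxdepth = ⌈log2(s+1)⌉ with cp = 0 (a depth-d binary tree has at most
2^d − 1 splits). Bagged trees treat the split budget as effectively
unlimited, capped at n − 1. Discriminant fits on degenerate folds (a feature
constant within a class) receive a vanishing jitter rather than failing.

`cross_validate()` uses label-stratified, seeded 10-fold cross-validation;
every row is predicted exactly once by a model that never saw it, and the
fold count is reduced with a warning when the smaller class is too small.
`exhaustive_feature_search()` evaluates all two- to five-feature
combinations plus the full eight-feature set (211 combinations).
`tune_best()` tunes the ensemble by a seeded random search over method,
learner count, learning rate and split cap; the default bagged-trees preset
is always the first candidate, so the tuned result can never fall below it
on the evaluated candidates. A sequential model-based optimizer would need a
surrogate-model dependency; with a four-dimensional, partly categorical
space and CV noise on the objective, seeded random search is a defensible
and reproducible substitute.

## Evaluation and channel selection

`compute_metrics()` evaluates accuracy, precision, recall, F1, specificity,
Matthews correlation, Cohen's kappa (in its two-rater binary form) and
fall-out exactly from the confusion counts; undefined ratios are flagged,
not returned as infinities. Because every formula is scale-free,
`confusion_from_rates()` can rebuild a normalized confusion matrix from a
printed sensitivity/specificity/prevalence triple — which is how the package
checks published per-channel tables for self-consistency. `roc_auc()` sweeps
thresholds over the unique scores; with ties this equals the rank
statistic, verified against exhaustive pair counting. Channel selection
(`select_coi()`) takes per-subject per-channel accuracies, picks the highest
channel mean, and runs two-sided paired t-tests against each other channel
at a Bonferroni-corrected threshold α/m with m = 5 by default (the winner
against the five remaining montage channels; two-sidedness is the
conservative choice where no direction is pre-registered).
`anova2_replicated()` provides the balanced two-way fixed-effects ANOVA used
for factor-level comparisons.

## The synthetic session generator

The study's raw recordings are not deposited, so `generate_session()`
emulates them. Its defaults are the package's definition of the study
conditions and were frozen as a single design pass:

* **Session structure.** 30-minute sessions at 125 Hz; alternating
  alert/drowsy dwells with shifted-exponential durations (floor = one 10-s
  window; means 60 s alert / 80 s drowsy, giving an expected drowsy
  prevalence of 80/140 ≈ 57.1%). The state process is started in its
  stationary regime, so that expectation holds at any session length. The
  labelling cadence of the original study is not described quantitatively;
  the dwell distribution is a package choice, not an inference.
* **Spectral structure.** Per band, zero-phase 4th-order Butterworth
  band-pass filtered Gaussian noise scaled by a state- and band-dependent
  amplitude gain (alert: δ/θ/α/β = 0.75/0.65/0.62/1.0; drowsy:
  1.2/0.95/1.05/0.9 before channel contrast), summed with a 1/f background,
  a flat sensor-noise floor typical of dry electrodes, 50/60 Hz line
  sinusoids, a 0.35 Hz breathing component and a 0.005 Hz drift. State
  transitions are cross-faded over 0.5 s so band edges do not ring.
* **Within-state variability.** Slow AR(1) lognormal gain fluctuations per
  band (sd 0.28, 20-s timescale; the three slow bands share a common
  component with correlation 0.5, reflecting their joint thalamocortical
  modulation), a mild continuous vigilance-depth drift around the labelled
  state (sd 0.1), phasic beta "engagement bursts" during alert periods
  (Poisson 10/min, 5 s, beta amplitude ×2.5 with a mild broadband
  component — alert-state beta rides on engagement episodes rather than a
  tonic elevation), and occasional state-independent beta desynchronization
  events (1/min, 2 s).
* **Between-subject variability.** Each synthetic subject perturbs all gains
  by a lognormal factor (sd 0.08) and the depth of drowsy beta suppression
  by a larger one (sd 0.2): how much beta falls during drowsiness is
  strongly subject-dependent, which is what makes beta-denominated ratios
  less consistent across a pooled cohort than the band powers.
* **Channel of interest.** The configured COI (F8 by default) applies a
  contrast multiplier (2.0) as an exponent on each slow band's drowsy/alert
  gain ratio — doubling the log-scale state contrast of the localized
  slow-wave/alpha response while treating beta suppression as spatially
  uniform.

These choices put the pipeline in the regime the method targets: pooled
cross-validated accuracy in the high-0.8s/low-0.9s on the COI, lower
elsewhere, with delta power the single most important feature. What the
generator does **not** emulate: realistic neural forward modelling and
volume conduction (channels are independent given the state), eye-blink and
muscle artifact morphology, slow circadian drifts of the vigilance baseline,
and any hardware specifics. Passing tests on synthetic sessions therefore
demonstrate that the pipeline recovers planted structure under realistic
noise — not that the same numerical performance would be reached on real
recordings.

One structural property of this generator class is worth stating openly:
because every feature is a smooth function of the same latent state, a
band-power ratio combines two aligned contrasts and, in rank terms, is at
least as discriminative as the weaker of its component powers. A fused
ranking in which all four band powers strictly precede all four ratios is
therefore not a stable outcome here — typically delta power ranks first
(it enters no ratio) and two to three band powers occupy the top four,
with one composite ratio interleaved. Reports on real cohorts that place
all four powers on top reflect properties of real recordings (estimator
heavy tails, artifacts, implementation details of the ranking routines)
that this generator intentionally does not chase.

## Numerical choices and degenerate inputs

Half-open windows `[i·10 s, (i+1)·10 s)` with 0-based indices; trailing
partial windows dropped. Constant features map to the lower rescaling bound
with a warning. A constant variable has zero mutual information with
anything. Empty χ² bins are merged before computing degrees of freedom.
ReliefF reduces k with a warning when a class is smaller than k + 1. AUC
ties are handled by rank-averaging. The EDF writer quantizes to 16 bits over
each channel's observed range and drops a trailing partial second with a
warning; CSV round trips are exact. All stochastic steps accept a single
seed, from which per-subject and per-channel streams are derived.

## Problem sizes used in the shipped checks

The package's own acceptance checks run the full pipeline on 600-second
sessions (60 windows per channel), 12 synthetic subjects, 6 channels and ten
independent seeds; channel selection in that sweep is evaluated with the
fast medium-tree preset (its channel ordering tracks the ensemble's), while
the headline classification number comes from the tuned ensemble on the
pooled COI table (720 windows). These sizes are the package's choice of a
desk-scale study; all of them are parameters, and nothing prevents running
the generator at the full 30-minute session length.

## Limitations

The pipeline is a faithful re-implementation of a published analysis
workflow, not a validated medical device. Its absolute performance numbers
on synthetic data say nothing about real-world detection rates; the
statistical machinery (stratified CV, paired channel tests, null
calibrations) is the transferable part. Known limitations: no artifact
rejection beyond fixed-band filtering, binary labels only, no online /
streaming mode, and ensembles re-implemented as thin wrappers (bagging,
AdaBoost, RUSBoost, random subspaces) over rpart/LDA/kNN rather than a
dedicated ensemble library.
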