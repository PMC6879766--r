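---
title: "Estimating the apnea-hypopnea index from cardiovascular features: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the apnea-hypopnea index from cardiovascular features: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed and graded with the
apnea-hypopnea index (AHI): the number of scored respiratory events per
hour of sleep, with conventional severity classes at 5, 15 and 30
events/h. The reference measurement, polysomnography, is costly and
obtrusive. Respiratory events, however, leave a reproducible imprint on
the cardiovascular system — a bradycardia while the airway is
obstructed, followed by an abrupt tachycardia, usually with an arousal,
when breathing resumes — so heart-rate dynamics extracted from a single
ECG lead (or any device yielding inter-beat intervals) carry usable
information about event occurrence.

`cardioahi` implements a complete pipeline from inter-beat intervals
(IBIs) and standard sleep annotations to an AHI estimate:

1. label 30-s epochs as respiratory-event (RE) epochs,
2. extract windowed cardiovascular features per epoch,
3. optimise each feature's class separability with a greedy chain of
   per-recording transformations,
4. train a balanced epoch classifier,
5. convert the detected RE-epoch fraction into events/h with a robust
   calibration slope, and grade severity.

A synthetic-recording generator with known ground truth closes the
loop: every stage, and the pipeline end to end, is testable without any
clinical data.

## RE-epoch labelling

Epochs are the standard 30-s scoring grid, half-open intervals
`[30k, 30k + 30)`. An epoch is an RE-epoch if

* a single respiratory event overlaps it by **at least 10 s**
  (inclusive), or
* it starts **strictly less than 5 s** after an event's end (the
  "after event" rule, which captures the apex of the post-event
  cardiovascular response).

Both readings are taken literally: `>= 10` and `< 5`. Two further
conventions were genuinely open and are fixed here: overlaps from
distinct events are *not* summed to reach 10 s (the rule speaks of a
single event), and an event ending exactly on an epoch boundary *does*
trigger the after-rule for the next epoch (distance 0 < 5). Epochs are
additionally characterised by the kind of their longest event
(`after_event` when positive purely through the 5-s rule), and the
after-combination tag distinguishes epochs with both triggers
(`after`), only overlap (`no_after`), or only the after-trigger
(`pure_after`). The implementation is validated against an independent
millisecond-rasterisation oracle on randomised event sets.

Hypopnea scoring differs between datasets (3% vs 4% desaturation
criteria); `harmonise_hypopneas()` drops hypopneas with desaturation
below 4% that are not followed by an arousal, so mixed corpora are
scored consistently. Hypopneas with no event detail at all are kept,
with a warning, by default — some public datasets provide none.

## IBI preprocessing

R peaks are detected with the classic Hamilton-Tompkins recipe
(band-pass 8-20 Hz, rectified derivative, moving-window integration,
adaptive threshold, 250 ms refractory period), then refined to the raw
signal's local extremum within ±50 ms. The refinement window is a
declared choice: it is narrower than half the shortest admissible IBI,
so refinement can never jump to a neighbouring beat, and the
polarity-agnostic extremum makes detection invariant to lead inversion.

IBIs outside `[0.5, 2]` s are rejected as non-physiological for sleep.
Ectopic beats produce a short coupling interval followed by a
compensatory pause; a pair of consecutive intervals whose ratio
(current over preceding) **exceeds 1.5** is therefore discarded in
full. The test is one-directional, range rejection runs first, and the
ratio is only evaluated for interval pairs that still share a beat —
ratios across rejected gaps are physiologically meaningless. Recordings
with more than 3% ectopic-tagged IBIs, or with 70% of the features
missing in more than 30% of epochs, receive an advisory exclusion
verdict.

## Feature extraction

Each feature family is computed over a window **centred** on the epoch
it is assigned to (centring follows from assigning the window to its
central 30-s epoch):

| family | window (s) | contents |
|---|---|---|
| `hrv_time` | 300 | 17 time-domain/distribution statistics (ms) |
| `hrv_freq` | 300 | VLF/LF/HF band powers, ratios, HF peak (Welch on 4-Hz resampled IBIs) |
| `dfa` | 360 | detrended-fluctuation exponents (short/long/full scales) |
| `dfa_progressive` | 60 | short-scale DFA exponent |
| `dfa_windowed` | 360 | mean sub-window DFA exponent |
| `sample_entropy` | 300 | SampEn(m = 2, r = 0.2 SD) |
| `multiscale_entropy` | 540 | SampEn at coarse-graining scales 1-20 |
| `activity_counts` | 30 | high-pass-filtered, rectified ECG amplitude per epoch |

A feature is computed only when valid IBIs cover at least **half of the
window** and at least **5 s (1/6) of the central epoch**; otherwise the
value is missing (`NA`), never a fill value. At record edges the
computation uses the truncated window but the coverage test keeps the
nominal window length, which makes poorly covered edge epochs go
missing — consistent with how missing features drive recording
exclusion. Spectral bands follow the HRV standards (VLF 0.003-0.04, LF
0.04-0.15, HF 0.15-0.4 Hz) on IBIs linearly interpolated to 4 Hz.
Families defined only in external methodological papers are not
re-implemented; the registry accepts plugins that participate in
optimisation and classification transparently. With every built-in
family enabled the matrix has 52 features.

## Transformation-chain optimisation

The separability score is the absolute mean standardized distance

$$\mathrm{AMSD} = \left| \frac{\mu_{RE} - \mu_{\bar{RE}}}{\sigma_{RE + \bar{RE}}} \right|,$$

computed over all pooled training epochs. Two details are unspecified
in principle and fixed here: the pooled standard deviation uses the
population (n-denominator) convention, and wake epochs are included in
the score (matching classifier training, which also sees all epochs); a
sleep-only variant is a configuration switch away.

The catalogue contains 22 transformations in 10 groups — clipping,
centring and scaling maps, distribution reshapers (Box-Cox with
post-z-scoring, histogram equalisation, quantile normalisation to
normal/exponential/uniform references, Tukey ladder), time shifts,
windowed dispersion and smoothing operators (7/15/23/31-epoch windows,
backward/forward/centred), second-order Butterworth low/high-pass
filters (cutoffs 0.25/0.5/0.75 in Nyquist-normalised units) and
exponent/log maps — 86 parameterisations in all. A directed graph (each
transformation's admissible input groups) constrains composition; the
raw feature is group 0. Chains are grown greedily: every legal
successor is applied per recording, the single best AMSD improvement is
kept, and the search stops when nothing strictly improves or at depth
five. Ties go to the first transformation in catalogue order, making
the search deterministic.

Further numerical choices:

* *Filters are zero-phase* (forward-backward), so filtered feature
  series stay aligned with their epoch labels; deliberate lags are the
  explicit time-shift transformation's job. Interior missing values are
  bridged by linear interpolation for the filter pass and restored to
  missing afterwards.
* *Tukey ladder* picks its exponent from
  {-2, -1, -1/2, 0 (log), 1/2, 1, 2} by minimising the per-recording
  absolute skewness; negative exponents are sign-flipped to preserve
  order.
* *Log, square-root and Box-Cox* shift each recording's series to
  strict positivity first (minimum mapped to a small epsilon).
* *Histogram equalisation* interpolates a 10-bin empirical CDF to
  `[0, 1]`; *quantile normalisation* maps ranks to the reference
  distribution's quantiles at `rank/(n+1)`; *amplitude scaling* divides
  by the per-recording maximum absolute value; *percentile* maps values
  to their normalised rank.
* The sliding median (the search's hot spot) is implemented in C++;
  all windowed operators ignore missing values inside the window.

The greedy depth-1 result is verified against exhaustive enumeration,
and randomly grown chains are checked against an independent encoding
of the group graph.

## Classification and calibration

RE-epochs are the minority class. Training data are first oversampled
to parity with SMOTE (synthetic interpolation between minority
neighbours, k = 5) and then cleaned with edited nearest neighbours
(3-NN leave-one-out vote, applied to both classes) to remove noisy
synthetic samples. Candidate models — logistic regression, a
Huber-loss linear scorer, LDA and QDA — are graded by mean
precision-recall AUC over participant-disjoint inner folds; the default
final model is elastic-net logistic regression. It is fitted by
glmnet's coordinate descent with a fixed penalty
(`lambda = 1e-3, alpha = 0.5`, both configuration-exposed), which is
deterministic and reproducible; a stochastic-gradient fit of the same
objective would add hyper-parameters without changing the model family.
Missing feature values are imputed with per-recording medians (falling
back to training medians when a feature is entirely absent in a
recording) before standardisation by the training means and population
SDs.

The AHI model is purely multiplicative:
$$\widehat{\mathrm{AHI}} = \beta \cdot \frac{\#\{\text{detected RE-epochs}\}}{\#\{\text{sleep epochs}\}},$$
with $\beta$ the Theil-Sen slope (median of pairwise slopes, equal-x
pairs skipped) relating the *true* RE-epoch fraction to the reference
AHI across training recordings. Because the model has no additive term,
only the slope is retained. The RE-probability threshold is chosen on a
0.01 grid by maximising the multi-class Cohen's kappa between estimated
and reference severity on the training recordings; ties resolve to the
**highest** threshold, deliberately favouring specificity. Both
calibration steps use sleep epochs only, while classifier training uses
all epochs. Severity bounds use inclusive lower edges (AHI ≥ 5 mild,
≥ 15 moderate, ≥ 30 severe).

Two tuning details matter for calibration. The elastic-net penalty is
chosen by inner-CV PR-AUC over participant-disjoint folds rather than
fixed a priori, and the probability threshold is selected on
**out-of-fold** probabilities from the same inner CV: in-sample
probabilities are over-sharp, and a threshold tuned on them transfers
poorly to unseen recordings.

## Evaluation toolkit

`agreement_report()` gives Spearman correlation (appropriate because
the estimate is heteroscedastically related to the reference, which the
Breusch-Pagan test quantifies), the Bland-Altman bias with limits of
agreement at ±1.96 sample SD of the differences, per-severity mean
errors, and flags for recordings mis-estimated by more than 30 events/h.
`screening_report()` evaluates the three canonical thresholds with
positivity defined as AHI ≥ t, builds ROCs over every distinct
predicted value, and reports the operating point closest (Euclidean) to
perfect sensitivity and specificity plus the 4-class severity confusion
matrix. `compare_correlations()` implements the Fisher-z test of equal
correlations. Cohen's kappa defines the degenerate both-raters-constant
case as 1.

## The synthetic generator

Simulation is IBI-level — every downstream computation consumes IBIs —
with an optional ECG rendering (template QRS convolution at the
simulated beat times plus baseline wander and, during movement bursts,
broadband EMG-like noise) used to test R-peak detection and activity
counts. Defaults describe a plausible sleeping adult and were fixed
once, a priori: baseline IBI 1 s (60 bpm), respiratory sinus arrhythmia
of 25 ms at 0.25 Hz, a 20 ms low-frequency component near 0.1 Hz, 25 ms
white noise, events lengthening the IBI by up to 15% (ramping over
10 s) with a 20% post-event shortening that peaks ~2 s after the event
ends and decays with a 4-s constant, a hypopnea-dominant event mix
(55/30/10/5%), log-normal event durations truncated to 10-60 s, a 15%
wake fraction in alternating bouts, sporadic ectopic beats (premature
coupling at 60% of the local IBI with a compensatory pause, injected
only where both intervals stay inside the physiological range so that
the ectopic rule — not the range rule — is what must catch them), and
~4 movement bursts/h. Events are placed only inside sleep bouts by a
renewal process whose exponential gaps are corrected for event-plus-
refractory occupancy, so the realised event rate tracks the target AHI;
the ground-truth AHI is the harmonised event count divided by hours of
sleep.

What the generator does *not* emulate: real QRS morphology variation,
respiratory-effort coupling, sleep-stage-dependent autonomic tone,
apnea-specific versus hypopnea-specific response differences, and
pathological arrhythmia beyond isolated ectopy. Passing end-to-end
tests therefore demonstrates that the pipeline's machinery recovers a
known signal of realistic shape and strength — not clinical-grade
performance on patients.

## The validation study

`synthetic_validation_study()` trains on 60 recordings and predicts 30
held-out recordings of 2 h each with the reduced feature set
(`hrv_time`, `hrv_freq`, `activity_counts`) — sizes chosen to exercise
every pipeline stage at a population scale that still runs comfortably
on a laptop core. It reports held-out Spearman correlation,
Bland-Altman bias and limits, screening metrics and severity accuracy;
`scripts/acceptance.R` is a thin wrapper that writes these numbers to
JSON.

## Known limitations

* The classifier is linear by design; non-linear interactions between
  features are only available through the transformation chains.
* β and the probability threshold are global, not per-severity;
  recordings with extreme event fractions compress the usable range of
  some per-recording normalisations (e.g. z-scoring a recording that is
  mostly events flattens the contrast the classifier relies on).
* In event-dense (severe) recordings almost every 300-s feature window
  contains events, so the classifier tends to over-detect RE-epochs
  there; because the threshold objective (severity kappa) is blind to
  within-class magnitude, this surfaces in the synthetic study as a
  severe-class overestimation of the AHI that the other classes do not
  show.
* Participants with heavy arrhythmia are outside scope — the 3%
  ectopic exclusion rule is a hard gate, mirroring the method's
  dependence on clean heart-rate dynamics.
* Feature families defined only in external methodological papers
  (arousal probability, adapted spectral analysis, high-frequency pole,
  local phase coordination, visibility graphs, Hilbert analysis) are
  exposed as registry extension points, not implemented.
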