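---
title: "Decoding a spatial auditory P300 paradigm: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a spatial auditory P300 paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiobci)
```

## The problem

A multi-class auditory brain-computer interface presents short sound cues
from speakers distributed around the listener. The attended direction is
rare from the listener's point of view (1 of 5, or 1 of 8), so attended
stimuli evoke an oddball response: a parietal positivity (P300) roughly
300-650 ms after the cue and an earlier fronto-temporal negativity around
100-300 ms. Decoding which direction a listener attends therefore reduces
to detecting, per stimulus, whether its EEG epoch looks "attended", and
combining those binary scores over repetitions into one multi-class
selection.

`audiobci` implements the complete offline chain: a synthetic EEG generator
that stands in for (undeposited) human recordings, preprocessing, a signed
ROC separability index with channel selection, a shrinkage-regularized
Fisher Discriminant under chronological cross-validation, and
selection-accuracy / information-transfer-rate evaluation, plus the
key-press control analysis for the behavioural condition.

## The condition matrix

Five conditions span the design space (see `condition_preset()`):

| condition | directions | reps/direction | trials | ISI (ms) | notes |
|---|---|---|---|---|---|
| C1000 | 8 | 10 | 32 | 1000 | onset latency jitter 25/14.4 ms; counting task |
| Cr    | 8 | 10 | 8  | 2000 | overt key press to targets |
| C300  | 5 | 15 | 50 | 300  | spatial + spectral cues |
| C175  | 5 | 15 | 40 | 175  | fastest stimulation |
| C300s | 5 | 15 | 20 | 300  | single speaker: no spatial cue |

These counts give 2560 (C1000), 3750 (C300), 3000 (C175) and 1500 (C300s)
subtrials per simulated session. Within a trial the stimulus order is
pseudo-random under two constraints: every direction occurs exactly once
per iteration block, and (BCI conditions only) at least two other
directions separate two presentations of the same direction, limiting the
overlap of target response windows at short ISIs. `generate_sequence()`
draws block permutations by rejection sampling with a retry cap and a
deterministic rotation-repair fallback; in practice a valid permutation is
found within a few draws.

## The synthetic EEG generator

The generator (`erp_templates()`, `noise_spec()`, `simulate_recording()`)
emulates the statistical structure the analysis relies on, not the full
physiology:

* **Stimulus-evoked response** (both classes): an N1-P2 complex
  (fronto-central Gaussian bumps at 100/180 ms, +/-3 uV). At 175-300 ms
  ISIs these overlap and sum linearly, producing the rhythmic evoked
  activity that partially masks the P300.
* **Attention effect** (target class only): a parietal positivity of 10 uV
  peaking at 430 ms (width 80 ms) and a focal frontal negativity of -5 uV
  at 200 ms. The amplitudes follow the measured grand-average peak range of
  attentive adults (about 4.5-12.5 uV parietal positivity, latency
  385-564 ms); `attention_scale = 0` removes both components, which is how
  the single-speaker control C300s is emulated - for a typical listener
  the pitch-only cue produces no reliable class difference.
* **Onset latency jitter** (C1000/Cr): per-stimulus shifts drawn from a
  normal distribution with mean 25 ms and SD 14.4 ms, truncated at zero
  (the family is a modelling choice; only the two moments are given).
  Jitter smears the grand average but leaves single responses intact.
* **Noise**: per-channel AR(1) background (coefficient 0.97) scaled to
  18 uV, a 5 uV 50 Hz mains component, and ocular blinks as a raised
  cosine of 120 uV/250 ms at 4 events/min on the EOG channels with a 15%
  frontal leak.

Two generator parameters deserve emphasis because no published value
exists for them. First, the ERP signal-to-noise ratio: the template
amplitudes are anchored to reported grand-average peaks, but single-trial
noise is free. The 18 uV default puts ocular rejection rates in the
single-digit percent range and single-subtrial classification in the high
80s. Second, homogeneity: every simulated response is an identical
template plus noise, whereas human single-trial ERPs vary in amplitude,
latency and topography. Synthetic decoding is therefore *easier* than
human decoding at matched amplitude - selection curves saturate after 2-4
iterations instead of 10-15, and bits/minute figures at one iteration are
far above anything reachable with real subjects. Passing tests show the
machinery is correct and leak-free, not that human-level difficulty is
reproduced.

## Preprocessing

`preprocess()` applies, in order: an order-8 Chebyshev II low-pass (30 Hz
pass edge, 42 Hz stop edge, 50 dB stop-band attenuation), decimation to
100 Hz, epoching to the half-open window [-150, 800) ms with the first
150 ms as baseline, and 70 uV ocular artifact rejection. Choices worth
recording:

* **Causal vs zero-phase.** The classification path filters forward-only,
  as an online system must; this delays peaks by the group delay. ERP
  summaries (`characterize_peak()`) use the zero-phase mode instead. The
  filter is designed from its stop-band edge; pass-band droop at 30 Hz is
  below 1.2 dB.
* **Filter-before-epoch.** Filtering runs on the continuous signal so
  epoch edges carry no transients; downsampling simply keeps every 10th
  sample because the 42 Hz stop edge is already below the 50 Hz Nyquist of
  the output rate.
* **Sample conventions.** At 100 Hz the window holds exactly 95 samples:
  15 baseline + 80 post-onset (the onset sample opens the post-baseline
  span). 80 post-onset samples decimate cleanly into 16 means of 5 - the
  feature grid below. The endpoints are a convention choice; the half-open
  form is the only one consistent with "16 post-baseline samples per
  channel".
* **Artifact rejection.** Each epoch's ocular channels are linearly
  detrended (the minimal drift model), then the epoch is masked if any
  sample deviates from the detrended baseline mean by more than 70 uV.
  Only ocular channels are scanned - the threshold is defined there and
  the method targets eye artifacts. Masked epochs stay in the timeline:
  they are excluded from training and scoring, but selection and transfer
  rates still account for their time. Epochs whose window leaves the
  recording are flagged and masked, never silently dropped.

## Separability and channel selection

`roc_index()` is the signed area between the ROC curve of target vs
non-target sample distributions and the diagonal, times two - equivalently
the rank-biserial correlation `2U/(n1*n2) - 1` with ties counted half.
Unlike t- or Fisher scores it assumes no Gaussianity and is invariant
under monotone transforms; it is computed per channel and time point
(`channelwise_roc()`), always on unmasked epochs, and within each
cross-validation fold on training data only.

`select_channels()` takes the 10 channels with the highest positive ROC
peak and the 10 with the lowest negative peak, searching the full
post-baseline window (the 300-650/100-300 ms windows are reporting
windows, not selection constraints). A channel may appear in both lists -
"10 + 10" is honoured literally, with `disjoint = TRUE` available; ocular
channels are excluded from selection since they monitor artifacts. Ties
break by channel index. One empirical caveat the tests encode: with short
ISIs (and even at 1 s, through the causal filter's undershoot) a target's
parietal positivity carries over into neighbouring - predominantly
non-target - epochs, so out-of-region channels can acquire genuinely
discriminative negative ROC peaks. Selections *concentrate* on the
parietal-positive/frontal-negative pattern rather than partitioning
perfectly.

## Decoding

Features are the 16 decimated post-baseline means per selected channel,
concatenated channel-major: 20 channels x 16 = 320 dimensions. Each
dimension is standardized with the training-set normalization vector
(population SD; degenerate dimensions get SD 1 and a warning), which is
stored and applied unchanged to test subtrials.

The classifier is a Fisher Discriminant whose pooled within-class
covariance is replaced by the analytic shrinkage estimate towards the
scaled identity `nu*I`, `nu = trace(S)/d` - the variant standard in ERP
decoding, with the intensity `gamma` given in closed form and clipped to
[0, 1] (`shrinkage_covariance()`). The empirical covariance uses the n-1
denominator. Weights are `w = Sigma^-1 (mu_nontarget - mu_target)`, so
targets score negative, and the bias centres the threshold midway between
projected class means; the bias affects only the binary score, never the
multi-class argmin.

`crossvalidate()` runs 10-fold cross-validation over *chronologically
contiguous* blocks whose boundaries never cut inside a trial (a trial's
subtrials must not straddle train and test, since selection is scored per
trial). Channel selection, normalization and classifier training all
happen inside the training folds - the leakage test corrupts one fold's
data and asserts that only that fold's model changes.

## Selection and information transfer

`select_target()` averages, per direction, the valid classifier scores
among the first k iterations and picks the most negative mean; directions
whose subtrials were all rejected are excluded, a fully empty trial counts
as an error with its time still counted, and ties resolve to the lowest
direction index. `selection_curve()` sweeps k, and `itr_report()` converts
accuracy P into bits/selection
`R = log2 N + P log2 P + (1-P) log2((1-P)/(N-1))` (with `0 log 0 = 0`) and
bits/minute `B = R * 60000 / (k * N * ISI)`. The timing model contains no
inter-trial pause or stimulus-duration term: this is the unique model that
reproduces the reconstructable published bits/minute cells to two decimals
(4.41 at P=0.90/k=15 and 6.25 at P=0.94/k=12 for N=5, ISI 300 ms; the
P=0.94/k=11 cell computes to 6.8163 and is printed as 6.81, one unit off
in the last digit). `max_itr_thresholded()` maximizes B over the iteration
counts reaching a 70% (usable) or 90% (reliable) selection score and
reports absence when the constraint is never met, as happens for the
no-spatial-cue control.

For the key-press condition, `score_key_responses()` assigns each press to
the earliest unconsumed stimulus whose onset precedes it by 150-1500 ms (a
configurable window; at the 2 s ISI the windows never overlap, and
reported reaction times of 360-612 ms sit comfortably inside it). The
error score excludes true negatives - correctly ignored non-targets would
otherwise mask the error: `error = (FA + misses)/(hits + FA + misses)`.
False alarms are normalized into per-opportunity rates: each target
presentation offers 2 direct neighbours and N-3 other directions on the
circular speaker layout (`neighbor_fa_rates()`). The published pooled
counts (14 neighbour and 19 other false alarms over 576 targets) give
1.22% vs 0.66%; the default sensitivity model uses exactly these rates,
and the pooled seven-subject simulation in `analysis/04_evaluate.R`
recovers the gradient.

## Problem sizes and numerical choices

The analysis scripts run the full condition matrix (50/40/20/32 trials).
The test suite exercises the same code paths on reduced sizes chosen as
the smallest that leave the tested contrasts unambiguous: end-to-end
decoding properties use 24 simulated trials (high-SNR C300) and the full
20-trial C300s control; distributional properties (chance levels,
permuted-label selection) use 2000 synthetic trials drawn directly at the
score level, which is exact enough for +/-3-point tolerances.

Other numerical conventions: reported percentages round half-up to the
printed precision of the corresponding tables; the ROC index is computed
via midranks (ties as half steps); `select_target` treats an all-NA
direction as absent rather than NaN; EDF serialization quantizes to 16
bits over the per-channel physical range (error bounded by range/65534)
and zero-pads the final one-second record.

## Known limitations

* Identical per-stimulus templates overstate decodability; trial-to-trial
  amplitude/latency variability, non-stationary noise and alpha rhythms
  are not modelled.
* The blink process has a constant rate, so rejection rates are roughly
  ISI-independent; human subjects blink more as long-ISI trials drag on.
* The channel list is 1-D with role tags; no electrode geometry, hence no
  topographic maps - the ROC/selection tables are written for an external
  plotting layer.
* Only the offline, binary-classifier analysis is implemented; online
  operation, adaptive stopping and genuinely multi-class classifiers are
  out of scope.
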