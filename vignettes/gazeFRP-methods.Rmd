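---
title: "Detecting intention in gaze: fixation-related potentials for a hybrid eye-brain interface"
author: "gazeFRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intention in gaze: fixation-related potentials for a hybrid eye-brain interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dwell-based gaze interfaces convert prolonged fixations into mouse clicks.
Because looking and commanding use the same behavior, every sufficiently
long spontaneous fixation also triggers a click — the *Midas touch*
problem. A hybrid eye-brain-computer interface (EBCI) tries to resolve it
by asking the EEG whether a threshold-exceeding fixation was *intended* as
a command. The physiological handle is a slow, parieto-occipital negative
wave — similar to the stimulus-preceding negativity that accompanies
feedback expectation — that builds up during fixations used for control
and is much weaker during spontaneous fixations of the same duration.

`gazeFRP` implements the complete offline analysis for this paradigm:

1. **Dwell detection** (`detectDwells`): the online selection criterion — a
   trailing window of 500 or 1000 ms whose gaze dispersion (max − min,
   per axis, blink samples excluded) stays within 2°, plus two refractory
   rules (no window overlapping the previous dwell; no click within a
   3 × 3° square around any click of the last 3000 ms). The click
   position is the blink-excluded coordinate-wise median.
2. **Fixation typing** (`labelFixations`): replaying the game's control
   state — button → control on; ball while control on → selection; next
   free cell → move completes, control off. Ball dwells with control off
   are the spontaneous (non-controlling) class; free-cell dwells with
   control off are too rare to analyze and are excluded.
3. **FRP preparation** (`rereferenceLinkedEarlobes`, `notch50`,
   `extractEpochs`, `baselineCorrect`): linked-earlobe reference, causal
   50 Hz notch, [−500, +1500) ms epochs at 500 Hz, 200–300 ms baseline.
   No high-pass filter is used anywhere in the feature path: with
   DC-coupled recording, a high-pass would smear saccade-related EOG
   steps into the analysis interval through its transient response.
4. **Features** (`extractFeatures`): mean amplitudes over 13 overlapping
   50-ms windows (200–250 … 440–490 ms) in 13 posterior channels —
   169 features, all inside the EOG-safe 200–500 ms interval and hence
   available before the 500 ms online decision point.
5. **Classifiers** (`buildCommittee`, `fitShrinkageLDA`): a committee of
   greedily selected one-dimensional threshold classifiers, and LDA with
   analytic shrinkage of the pooled covariance.
6. **Evaluation** (`runCV`): stratified 5-fold rotation with a dedicated
   validation fold per rotation used solely to calibrate the decision
   threshold to a 0.90 specificity target, per-type sensitivities, AUC,
   and the false-alarm-per-minute arithmetic.

No public recordings exist for this paradigm, so the package ships a
forward model (`simulateSession`) that generates gaze + EEG sessions with
the statistical structure the analysis assumes; every pipeline stage is
tested against it.

## The forward model and its calibration

A session consists of four 5-minute games per dwell-threshold condition.
Moves are triplets of controlling fixations (button → ball → free cell),
each held one threshold plus a 200–300 ms feedback linger. After every
4–8 moves the button disappears for 10 s (a planning pause): the player
can only look around. Between moves and during pauses the model emits
spontaneous fixations on balls, back-to-back, separated by 40-ms
saccades.

Two behavioral anchors calibrate the spontaneous fixation durations, both
taken per 4-game block: about 158.6 spontaneous dwells of ≥ 500 ms in the
500-ms condition and about 10.8 of ≥ 1000 ms in the 1000-ms condition.
With a log-normal duration model, the ratio of the two exceedance
probabilities and the count rate per second of spontaneous viewing give
two equations; solving them at the session's spontaneous-time budget
(~844 s per 500-ms block at 7.5 moves/min) yields `meanlog = -1.808`,
`sdlog = 0.66` (median 164 ms, mean 204 ms — ordinary scanning
fixations). These defaults are study conditions, not tuning knobs.

The EEG is assembled per channel as:

* **pink (1/f) noise**, sd 10 µV, independent across channels — the
  simplest background that still exercises averaging and single-trial
  classification (no spatial covariance model, see Limitations);
* a **lambda wave**: a 50-ms half-cosine peaking 100 ms after every
  fixation onset at Oz/O1/O2/POz, identical across fixation types (the
  empirical lambda shows no control dependence, which is also why the
  baseline is placed after it);
* the **anticipatory negativity** (`spnComponent`): a linear ramp from
  300 ms after fixation onset to fixation end, scaled by a spatial
  profile peaking at POz. The ramp is normalized so that the discrete
  mean over the 400–498 ms sample grid equals the configured amplitude
  exactly (the grid's mean time is 449 ms). Defaults: button −5.3 µV and
  non-controlling −2.0 µV (anchored to the grand means reported for this
  paradigm); ball −3.5 and free cell −1.5 µV are free parameters chosen
  to reproduce the observed within-triplet ordering. With the ramp onset
  at 300 ms — the end of the baseline window — the configured amplitude
  is exactly the expected baseline-corrected measurement; an earlier
  onset would be partially absorbed by the baseline (the config allows
  overriding it);
* a **button-side asymmetry**: ± half the configured PO4 − PO3 difference
  (left −0.4, right +2.2 µV) added to PO4/PO3 with the same ramp shape;
* **EOG**: the corneo-retinal dipole modeled as gain × gaze angle
  (16 µV/°) split antisymmetrically across the electrode pairs, blink
  excursions of 100 µV on the upper vertical electrode, a small leak into
  frontal channels, and a configurable (default zero) leak into posterior
  channels.

Blinks are placed inside long spontaneous fixations, never inside
controlling dwells (online control succeeded, so those dwells were
blink-free).

## Numerical choices

* **Half-open intervals everywhere.** The epoch is [−500, 1500) ms —
  exactly 1000 samples; feature windows are [start, start + 50) on the
  2-ms grid — exactly 25 samples; the baseline is [200, 300) — 50
  samples. Printed interval notations leave endpoint inclusion
  ambiguous; half-open sampling makes every count exact.
* **Causal filters.** Both Butterworth filters (48–52 Hz band-stop, 7 Hz
  low-pass) run forward-only, so the chain could operate online without
  look-ahead. The 4-Hz stop-band width is the conventional mains-notch
  choice. The 7 Hz low-pass is display-only and never precedes feature
  extraction.
* **Onset convention.** A dwell's onset is click time minus threshold.
  When a short saccade precedes a fixation, the in-flight samples close
  to the target already satisfy the dispersion bound, so online clicks
  can lead the true fixation onset by a few milliseconds (up to ~15 ms
  for one-cell moves under the main-sequence saccade model). Configured
  amplitudes are defined relative to the *true* onset; parameter-recovery
  tests therefore align epochs on ground-truth onsets, while ordering and
  classification checks run the fully detected pipeline.
* **Weak-classifier search.** Candidate thresholds are the midpoints of
  adjacent distinct sorted values plus ±∞, both polarities; ties break
  toward the smaller threshold, then polarity +1, making fits
  deterministic. The implementation is an O(n log n) cumulative-count
  scan, validated in the tests against an O(n²) brute-force oracle.
* **Committee voting.** During greedy selection a provisional committee
  of size m predicts target iff votes > m/2; an exact half votes
  non-target (conservative, specificity-first). The *operational*
  threshold is not majority vote but the specificity-calibrated vote
  count — the paradigm calibrates "thresholds for the classifiers" for
  both methods.
* **Selection error.** Weak classifiers and the committee minimize the
  balanced error (mean of the two class error rates) by default: classes
  are ~3:1 imbalanced and the goal is specificity-oriented. The plain
  error rate is available via `errorType = "plain"`; the original
  committee's exact functional is not recoverable, so both are offered
  and the default documented.
* **Shrinkage intensity.** The Ledoit–Wolf-type analytic estimator on the
  class-centered cross products, clipped to [0, 1], computed per training
  fold only — never on validation or test data. `γ = 1` gives
  `w = (μ₁−μ₀)/ν` exactly; `γ = 0` recovers classical LDA.
* **Threshold calibration.** The smallest threshold whose validation
  specificity reaches the target (maximizing sensitivity subject to the
  bound). With continuous LDA scores the achieved test specificity sits
  tightly at the target; with 16-level committee vote counts it
  overshoots by discreteness — the tests assert the tight band for LDA
  and a coarser [0.85, 0.97] band for the committee.
* **Cross-validation scheme.** The original train/validation/test
  partition is not recoverable, so each of the 5 rotations uses 3 folds
  for training, 1 for calibration, 1 for testing, stratified by class and
  fixation type. Under trainset variant 1 (button-only targets),
  ball/free-cell epochs never enter training folds; they are scored as
  held-out strata with every rotation's model and averaged.
* **Artifact handling.** Epochs with |amplitude| > 70 µV anywhere in
  200–500 ms in any EEG channel are *counted*
  (`countArtifactEpochs`) but never removed — EOG safety comes from
  interval selection, not rejection. Absolute value is used; the census
  is reporting only.
* **Degenerate inputs.** Zero-duration games yield empty schedules, not
  errors; single-class training data, all-blink dwells, missing
  electrodes and double baseline application raise errors; out-of-bounds
  epochs are skipped with a logged count.

## What the tests do and do not show

The test suite validates the machinery on data whose generating process
is known: dwell detection is compared sample-by-sample against a
brute-force oracle; classifier fits against exhaustive search; amplitude
recovery against the configured forward model (8 simulated participants,
4 × 5-min games each, grand means within 2 standard errors, button more
negative than non-controlling in 8/8). Problem sizes in the acceptance
checks — 100 random 60-s traces, 50 random classifier instances, 20
calibration seeds, an 8-participant study of one 4-game block — were
chosen to make the statistical assertions sharp at desk scale.

Passing these tests shows the pipeline is faithful to its specification,
not that real EEG behaves like the model. In particular the forward model
omits: spatial correlation of the background EEG (shrinkage LDA faces a
harder covariance problem on real data), trial-to-trial amplitude and
latency variability of the negativity beyond what pink noise induces,
saccadic spike potentials and other myogenic artifacts, drift and
calibration error of the eye tracker, and any dependence of component
amplitude on saccade size or fixation position. Classification numbers
obtained on synthetic sessions are therefore indicative, not predictions
of human performance.

## Known limitations

* The committee's vote-count AUC is coarse (16 levels) and not comparable
  with the LDA's continuous-score AUC; it is reported but the
  discrimination assertions use the LDA.
* `labelFixations` assumes a static board per game (no ball movement or
  line completion); move legality is not modeled.
* The simulator's games are contiguous in one recording; real sessions
  have inter-game breaks and re-calibrations.
* Repeated-measures MANOVA and post-hoc structure of the behavioral
  analysis are out of scope; only the paired laterality t-test is
  implemented.
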