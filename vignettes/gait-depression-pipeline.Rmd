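---
title: "Recognizing depression from skeleton gait data: models and methods"
author: "gaitdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing depression from skeleton gait data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdep)
```

## The problem

Psychomotor changes are a core sign of major depression, and several of
them surface in gait: reduced walking speed and arm swing, slumped head
posture, shorter strides, diminished vertical head movement. A depth
sensor of the Kinect v2 class captures the 3-D positions of 25 body joints
at 30 Hz while a participant walks naturally back and forth on a short
(~6 m) footpath for about two minutes, yielding a `T x 25 x 3` trajectory
per person. `gaitdep` implements the complete analysis of such recordings
for a case/control cohort: preprocessing into a canonical two-gait-cycle
segment, three banks of gait features, a logistic-regression analysis of
how much variance in diagnosis each bank explains, and a cross-validated
SVM classifier over every combination of the banks.

Clinical recordings of this kind cannot be redistributed, so the package
ships a synthetic-cohort generator whose group-level kinematics encode the
published case/control summary statistics of a 247-participant clinical
cohort (126 cases, 121 controls). All tests and the acceptance script run
against these synthetic cohorts.

## Preprocessing

**Coordinate transform.** Raw positions are sensor-frame (X to the
sensor's left, Y up, Z out of the sensor). Subtracting the same-frame
spine position from every joint removes whole-body translation; the
sensor-frame spine trajectory is retained because walking speed is only
measurable there (in the spine-relative frame the spine is identically
zero).

**Pass segmentation.** Back-and-forth walking alternates face-toward and
back-toward passes. Facing is not directly observed, so passes are defined
by the sign of the smoothed spine-Z velocity (negative = approaching the
sensor); direction flickers shorter than 1 s (a tunable minimum) are
merged into the preceding pass. Only face-toward passes are used, and of
the k face-toward passes the ceiling(k/2)-th is selected — the middle of
the walk, away from start/stop artifacts — with ties broken toward the
earlier pass for determinism.

**Gait-cycle segmentation.** A gait cycle starts at left-toe toe-off. The
toe-off is operationalized on the Gaussian-filtered spine-relative
left-toe Y trajectory as a strict local minimum that (a) lies in the
bottom 30 % of the series range (the toe lifts from the ground, so
candidate minima on swing flanks are rejected), and (b) is followed within
the 0.5 s refractory window by a rise of at least 12 % of the range.
Events closer than 0.5 s to the previous kept event are discarded. The
final segment spans the central three toe-off events — exactly two
cycles — and typically lasts 1.7–3.4 s. If a pass holds fewer than three
events (a fast walker on a short path), adjacent face-toward passes are
tried in order of distance from the middle.

**Filtering.** Every channel is convolved with the unit-sum binomial
kernel `(1/16)[1, 4, 6, 4, 1]`, a small Gaussian low-pass that removes
sensor jitter while attenuating gait-band signals by under 2 %.
Boundaries are handled by edge replication, which preserves the filter's
unit DC gain at the segment ends (zero padding is available). Toe-off
detection runs on a filtered copy of the toe trajectory; the stored
segment is filtered once, after cropping, so no channel is filtered twice.

## Feature banks

* **Spatiotemporal (10).** Per cycle, averaged over the two cycles: body
  sway (max shoulder-to-shoulder X difference), left/right arm swing
  (peak-to-peak wrist Z), vertical head movement (peak-to-peak head Y),
  head posture (mean angle between the vertical and the neck–clavicle
  line in the Y–Z plane, radians; degree conversion available), left/right
  stride (peak-to-peak foot Z), left/right toe clearance, and walking
  speed (|spine Z displacement| / duration, from the retained sensor-frame
  track). Toe clearance is reported as the *maximum* spine-relative foot
  Y rather than a max−min range: a spine-relative foot height is negative
  (the foot is below the spine), and the published group summaries this
  package mirrors print negative toe-clearance values near −0.7 m, which
  a nonnegative range could never produce. A `range` mode is available.
* **Time-domain (300).** Mean, SD, skewness, kurtosis per channel
  (75 channels x 4). Conventions: sample SD with n−1; skewness
  `g1 = m3 / m2^{3/2}` and excess kurtosis `g2 = m4 / m2^2 − 3` with 1/n
  central moments; a zero-variance channel has skewness and kurtosis
  defined as 0 so degenerate inputs stay finite.
* **Frequency-domain (825).** Per channel, from the DFT over the full
  segment: the DC component `F_0 / n` (the signal mean) plus mean,
  variance, SD, skewness and kurtosis of the amplitudes `|F_k|` and of the
  principal-value phases `arg(F_k)` over k = 1..n−1 (both variance *and*
  SD are part of the bank's definition, hence 1 + 5 + 5 = 11 per channel).
  The full two-sided index range follows the transform's definition; no
  amplitude floor is applied to phases by default (a floor is
  configurable), so phase statistics of noise-dominated bins behave as
  draws from a symmetric distribution — a known, accepted property.

## Inference

Group differences in the spatiotemporal bank are summarized by pooled
two-sample t tests (df = n1 + n2 − 2). The time- and frequency-domain
banks are z-scored and reduced by PCA to the smallest number of components
reaching 95 % cumulative explained variance (zero-variance features — the
spine channels, identically zero in the spine-relative frame — are dropped
with a warning). Component signs follow a deterministic convention (the
largest-magnitude loading is positive).

Stepwise forward logistic regression then selects predictors: starting
from the intercept, the candidate with the smallest likelihood-ratio entry
p-value is added while that p-value is below alpha = 0.05 (Wald entry is
available). Selection operates on raw p-values; the Holm correction
(Bonferroni optional) is applied to the final model's terms for reporting
only — this is why reported tables can retain terms whose corrected p
exceeds alpha. Per term the fit reports beta, SE, Wald = (beta/SE)^2,
OR = exp(beta), raw and corrected p. Model-level explanatory power is
Nagelkerke's R², the Cox–Snell pseudo-R² rescaled to [0, 1]. Fitting is
Newton–Raphson/IRLS to a 1e-8 step tolerance (max 100 iterations);
perfect separation is detected by scale-invariant heuristics and reported
through a weakly ridge-penalized refit with a warning.

With ~100+ PCs as candidates and alpha = 0.05, forward selection admits a
non-trivial number of noise components by construction (each step screens
every remaining candidate); selected models on strongly separable
synthetic cohorts therefore reach higher R² than a parsimonious model
would. This is a faithful property of the procedure, not a defect, and is
why the per-bank R² values on synthetic cohorts should be read as a
direction (stride-level bank far below the signal-domain banks), not as
calibrated magnitudes.

## Classification

A linear-kernel SVM (penalty C = 1, configurable) is evaluated by
stratified 10-fold cross-validation; standardization is fitted on each
training fold only. Sensitivity (cases positive), specificity and AUC
(midrank/Wilcoxon form, so tied scores are handled exactly) are averaged
across folds; ROC points are pooled out-of-fold scores, used for plotting
only. All seven nonempty combinations of the three banks are evaluated
under an identical fold assignment so rows are comparable.

For classification the time/frequency banks enter as their retained PC
scores (`reduce = "pca"`, default) on their natural scale, with each
block normalized to unit total variance before concatenation; the
10-feature spatiotemporal block is z-scored. Re-standardizing PC scores
per fold would inflate the ~100 near-zero-variance components of each
bank to unit weight and bury the signal — an instructive failure mode we
document rather than repeat. Classifying raw features
(`reduce = "none"`, per-fold z-scoring) is available.

Sequential backward selection (SBS) is implemented as specified by its
greedy rule — repeatedly drop the feature whose removal maximizes mean
k-fold CV accuracy, accept while the measure does not decline (ties favor
the smaller set) — and is exercised by the tests. It is off by default in
`run_analysis()`: with ~250 PC candidates the evaluator costs O(p²)
cross-validated SVM fits per cohort, and on PCA-reduced inputs its
benefit is modest. The default pipeline therefore reports
selection-free cross-validated performance; `sbs = TRUE` enables it for
compact feature sets.

## The synthetic-cohort generator

Each walker is a constant-speed spine trajectory ping-ponging along the
footpath, with every joint a fixed anatomical offset from the spine plus
sinusoidal oscillators at the gait frequency (arms and legs in antiphase;
left/right in antiphase). Group structure enters through per-parameter
truncated-normal draws whose means/SDs are the published case/control
summary statistics (arm swings, strides, body sway, head posture, toe
clearances, walking speed), a shared cycle-duration distribution centered
at 1.185 s truncated to half the observed two-cycle range, sensor noise
(5 mm Gaussian plus a 3 mm 13.7 Hz jitter tone), and four
waveform-*shape* parameters that differ between groups:

* a second-harmonic ratio and phase (waveform asymmetry; mild contrast),
* a per-cycle transient "hitch" on wrist and foot trajectories — a brief
  mid-swing hesitation whose depth differs by group; it is mostly visible
  to the time-domain moments,
* a 5 Hz low-amplitude tremor on lateral hand/head channels that ride on a
  fixed-amplitude postural wobble; the wobble masks the tremor's variance
  contribution from the time-domain moments while its spectral line stays
  isolated for the amplitude statistics,
* a gait-phase lag of all oscillators relative to the toe-off-anchored
  cycle start (the toe trajectory itself is not lagged); over whole cycles
  this leaves every time-domain marginal and every peak-to-peak feature
  exactly invariant and moves only the spectral phases.

Limb waveforms are renormalized to unit peak-to-peak before scaling, so
shape parameters never leak into the spatiotemporal amplitude features;
the toe trajectory has a cusp-shaped minimum so the detected toe-off stays
pinned under noise. The shape contrasts were calibrated once, at design
time, so that a full-size default cohort reproduces the qualitative
structure of the clinical result — stride-level features weakest
(AUC ≈ 0.7 here; the clinical value is lower), each signal-domain bank
clearly stronger (≈ 0.83–0.90), and the combined time+frequency model at
least as good as either alone. Across replicate cohorts this ordering
holds in the large majority of runs; because the default pipeline applies
no per-combination feature selection, the combined-vs-best-single
comparison can occasionally invert within fold noise (≈ 0.005 AUC) on
some seeds.

What the generator does **not** emulate: biomechanical constraints
(ground reaction, balance), occlusion and tracking dropouts, turning
dynamics at the path ends (the spine reverses instantaneously),
facing-dependent mirroring, and any within-walk nonstationarity. Passing
tests on synthetic cohorts therefore validate the *pipeline's
computations and their documented properties*, not clinical effect sizes:
the published per-bank R² (12.55 / 58.36 / 60.71 %) and classification
table (best sensitivity 0.94, specificity 0.91, AUC 0.93) require the
original patient recordings, which are unavailable.

## Numerical choices and degenerate inputs

* Convolution boundaries: edge replication (configurable); filter length
  requires ≥ 5 frames.
* Toe-off: 0.5 s refractory, 12 % rise, 30 % depth; a flat trajectory is
  a segmentation error, fewer than three events in every face-toward pass
  propagates an "insufficient gait cycles" error.
* Zero-variance channels: moments defined with skew/kurt = 0; PCA drops
  the feature with a warning; PC–feature correlation reports NA.
* Two-sample t with both SDs zero and equal means is defined as 0.
* Stepwise ties: the smallest entry p wins by index order; SBS ties favor
  the smaller feature set.
* Stratified folds require every class to have at least k members.
* AUC uses midranks, so ties contribute 1/2.
* Problem sizes: unit tests run cohorts of 8–24 walkers at 30–60 s;
  cohort-level claims (segment-duration range, AUC ordering) are tested on
  one full-size default cohort (247 walkers, 120 s, seed 1), the same
  conditions the acceptance script reruns.

## Known limitations

* The generator is a stand-in: its shape-effect channels are constructed,
  not measured, and magnitudes of R²/AUC on synthetic cohorts are not
  calibrated to the clinical values.
* Forward selection over many PCs is anticonservative at model level (see
  above); corrected per-term p-values are reported but model-level
  optimism is not corrected.
* SBS over hundreds of features is computationally prohibitive with a
  cross-validated SVM evaluator and is not part of the default run.
* Joint indices other than the eleven anatomically cited roles follow this
  package's canonical map; recordings using a different 25-joint
  convention must be re-indexed on import.
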