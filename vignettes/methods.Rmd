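---
title: "Methods: simulating, detecting and classifying joint-impaired gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, detecting and classifying joint-impaired gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Restricting a knee or ankle changes a walker's sagittal-plane kinematics in
characteristic ways: the braced knee loses most of its flexion range, the
braced side's swing lengthens, and left/right symmetry degrades. `imugait`
implements a complete pipeline for studying whether two measurement systems —
bilateral thigh/shank inertial sensors (IMUs) sampled at 50 Hz, and a
pressure-sensitive walkway that records footfall positions and contact
times — can discriminate normal walking from knee-restricted and
ankle-restricted walking, and the two restrictions from each other.

Because raw cohort recordings of this design are not publicly deposited, the
package is anchored by a synthetic cohort generator calibrated to published
descriptive statistics of brace-restricted gait (per-condition means and SDs
of segment ranges of motion, cycle/swing/stance times, step geometry, and
symmetry ratios). Every downstream stage — event detection, parameter
extraction, feature selection, classification, repeated-measures testing —
operates identically on simulated or real tabular inputs.

## The synthetic gait model

A cohort is `n_subjects x 3 conditions x n_trials` straight walks
(default 10 x 3 x 10, mirroring the study design the calibration targets
come from: ten healthy adults, ten trials per condition, a 5 m path at
self-selected speed).

**Drivers and emergent parameters.** For each trial the generator draws a
small set of *driver* descriptors around the condition targets: common cycle
time, per-leg swing times, per-leg shank and knee sagittal ranges of motion
(ROM), step lengths, step times, walkway swing times, and base of support.
Everything else *emerges*: stance = cycle − swing, phases, cadence =
60/cycle time, stride length = left + right step, support times from the
footfall overlap pattern, and the symmetry ratios from the paired left/right
values. Emergent quantities are the honest test of the model: they are
compared against their published targets in the test suite without being
drawn directly.

**Variance structure.** Each driver's total variance (the published SD,
squared) is split 60%/40% between subject level and trial level
(configurable via `variance_split`); a subject's standard-normal offsets are
drawn once and reused across conditions, which produces the within-subject
consistency that repeated-measures tests rely on. Left/right values of a
parameter are correlated within subject (0.7) and within trial (0.5) —
independent draws would propagate roughly twice the published spread into
the symmetry ratios — and the four angular drivers share a per-leg
restriction factor. The thigh ROM is not drawn independently: the waveform
geometry (below) floors it at shank ROM − knee ROM, so it is generated as
that difference plus a positive lognormal gap whose mean reproduces the
published thigh target. Draws violating physical constraints (non-positive
times, stance or swing below 0.43 s, degenerate ROMs) are rejected and
redrawn, at most 100 times before the trial fails.

**Waveforms.** The shank sagittal angle over one gait cycle is the integral
of a prescribed angular-velocity shape: a flat, mildly negative stance
baseline; a sharp trough at toe-off; a broad backward lobe in early swing; a
dominant positive lobe in mid-swing; and a sharp trough at heel strike. The
lobe amplitude is set so the angle closes its loop over the cycle. This
gives the finite-differenced signal exactly the trough/peak signature the
event detector keys on, with trough prominences far above the 20 deg/s
detection threshold at all calibrated amplitudes. Knee flexion is the
rectified negative excursion of the shank template (flexion mirrors the
backward shank swing), and the thigh angle is *defined* as shank + knee, so
the conventional knee angle (thigh − shank) is reproduced exactly. One free
shape parameter — a phase shift of the knee flexion bump — is solved per
trial (grid bracket plus root refinement, then one measure-and-correct
re-render against the realised sampled ROM) so the thigh ROM meets its
target. Per-cycle timing jitter (1.5%), amplitude jitter (2%) and smoothed
0.15 deg sensor noise are superimposed. Each trial renders five complete
cycles per leg plus lead-in/lead-out cycles; ground truth contains every
heel strike and toe-off whose labelling context (the mid-swing peak) lies
inside the record, minus a 0.25 s edge guard applied identically by the
detector.

**Walkway model.** Footfalls alternate sides along the walkway, advancing
by the drawn step lengths (1.5 cm placement noise) with lateral offset
± base of support / 2 (0.3 cm noise); contact times advance by the drawn
step times, and foot-off times are placed so each foot's swing matches its
drawn walkway swing time. The walk ends when the path is covered and both
feet have at least four contacts. Because a fixed-length walkway yields more
strides from faster trials, per-cycle averages are mildly length-biased —
exactly as in real walkway data.

**Reproducibility.** One root seed; every (subject, condition, trial) gets
its own RNG stream by stable hashing, so enlarging a cohort never perturbs
existing trials, and two cohorts with the same seed export bit-identical
tables.

**What the generator does not emulate.** No 3-D or frontal/transverse
kinematics, no kinetic (force) signals, no raw accelerometer/gyroscope noise
beyond additive angle jitter, no turning, fatigue or trial-order effects,
and no inter-parameter correlations beyond the bilateral/leg-factor
structure above. Passing tests therefore demonstrate that the pipeline
recovers what this model encodes — calibrated first and second moments and
event timing — not that it would classify real patients at the same
accuracy.

## Event detection

Heel strikes and toe-offs are detected on the shank sagittal angular
velocity with a topographic-prominence peak finder (prominence 20 deg/s,
minimum separation 20 samples, applied separately to the raw and negated
signal). Per cycle the dominant mid-swing positive peak is located first —
"dominant" means exceeding 0.3x the trial's maximum velocity, which
excludes stance-plateau noise bumps whose topographic prominence is
inflated by the flanking event troughs. The trough immediately before a
mid-swing peak is labelled toe-off and the trough immediately after heel
strike; a trough claimed by two peaks, or a non-alternating result, raises
an error (this is what a time-reversed or non-gait signal triggers). Events
within 0.25 s of the record edge are dropped as context-incomplete. The
published protocol's manual verification step is replaced by these
automated ordering checks.

## Gait parameters

Per paired cycle the IMU vector holds 21 named values: per leg, shank ROM,
thigh ROM, knee ROM (per-sample thigh − shank, then max − min inside that
leg's own cycle window), cycle time, cadence, swing/stance times and phases;
plus three symmetry ratios,

- TSR = (swing_R/stance_R) / (swing_L/stance_L),
- SSR1 = (shank_R/thigh_R) / (shank_L/thigh_L),
- SSR2 = knee_R / knee_L.

Cadence is 60/cycle time — cycles (strides) per minute — matching the
magnitude of the published descriptive table even though its unit label
says steps; the discrepancy is inherited from the source material.
Swing is defined as toe-off to the next heel strike (the biomechanical
convention), and the ratios are computed per cycle pair rather than from
trial-mean leg values, both genuinely open choices in the source protocol.

The walkway vector holds 25 values per left-anchored gait cycle: per leg,
step length, stride length, base of support (lateral distance to the
opposite foot's least-squares line of progression), step/stride times,
swing/stance times, single and double support times (interval arithmetic on
the contact intervals), stride velocity, phases; plus TSR. Field-standard
definitions are used throughout, since the original device computes these
internally. Right-leg stride-spanning fields are `NA` when the record ends
before the right foot's next contact; cohort tables keep complete rows only.

## Classification

The sample unit is one cycle pair (IMU) or one gait cycle (walkway); all
cycles of a subject stay on one side of every split (grouped 5-fold
cross-validation — identity leakage would otherwise dominate at these
cohort sizes). Tasks: normal-vs-abnormal (knee and ankle pooled), the three
pairwise tasks, and three-class. Classifiers: linear-kernel SVM
(`e1071`), random forest with the gini criterion and 100 trees (`ranger`),
and gradient-boosted trees (`xgboost`, eta 0.3, depth 6, 100 rounds;
softmax/logistic objective — a regression objective is not meaningful for
this task). Feature selection is recursive elimination within each training
fold (drop the least important feature per round: squared margin
coefficients for the SVM, impurity importance for the forest, split gain
for boosting); the subset size maximises fold-mean accuracy (ties toward
fewer features) and the final subset is a majority vote across folds at
that size, ties broken by mean full-model importance. Accuracy, precision,
recall and F1 are computed from the one-vs-rest confusion counts with
support-weighted averaging; per-fold metrics, their mean, and the
fold-aggregated confusion matrix are reported. Hyperparameter tuning is
deliberately off by default for reproducibility; `classifier_spec()`
accepts overrides.

Note that `e1071`/libsvm resolves multi-class SVM by one-vs-one voting;
the original protocol's `ovr` flag only changes sklearn's decision-function
shape, not the libsvm fit underneath.

On calibrated cohorts the IMU system separates the three conditions almost
perfectly (the braced knee's ROM and SSR2 are near-disjoint across
conditions) while the walkway system confuses knee and ankle restriction —
the same directional pattern, produced by the same mechanism (angular
parameters carry the joint-specific signal; spatio-temporal parameters do
not), as in the study the calibration targets come from. The absolute
accuracies here describe this synthetic model, not any real cohort.

## Statistics

The statistical unit is the subject: cycles are averaged per
(subject, condition), giving 10 x 3 matrices per parameter. The Friedman
statistic S = 12/(nk(k+1)) sum_j R_j^2 − 3n(k+1) is computed from within-subject
ranks (average ranks on ties) and referred to the chi-square upper tail
with k − 1 degrees of freedom — for k = 3, p = exp(−S/2), which is the
convention the published p-values follow exactly (every printed pair
matches at 4 decimals, e.g. 0.6 → 0.7408). Post hoc, paired Wilcoxon
signed-rank tests (zero differences dropped; exact two-sided p by full sign
enumeration for n ≤ 12, normal approximation with tie and continuity
correction beyond) with Bonferroni-corrected thresholds 0.05/3 and 0.01/3
localise the effects. The descriptive report rounds statistics to 1 d.p.,
p-values to 4 d.p., and means/SDs to 2 d.p.

## Numerical and design notes

- **Calibration tolerance.** The generator is validated at the study size
  (10 subjects x 10 trials) by requiring cohort means of every parameter
  with a clear condition effect to fall within 2 printed-SD/√10 of the
  printed mean, at a fixed seed. The printed table is itself rounded and in
  places internally inconsistent (phase 0.44 vs swing/cycle = 0.49/1.12 =
  0.4375; normal-condition double support 0.26 vs stride − both swings =
  0.27); derived parameters are therefore checked against the
  identity-consistent value implied by the printed drivers. The thigh rows
  carry no condition effect (published Friedman p = 0.90/0.30) and are
  outside the calibration set.
- **Problem sizes.** Tests and the acceptance checks run on 10 x 10 x 3
  cohorts (300 trials, ~1200 IMU cycle pairs) for calibration, detection F1
  and the system-ordering checks (five seeds), and on small constructed
  fixtures everywhere else; these sizes were chosen as the smallest that
  pin down the claims being tested.
- **Determinism.** All stochastic fits receive derived stream seeds;
  `ranger` and `xgboost` run single-threaded in the pipeline, so a seed
  fully determines every report.
- **Degenerate inputs.** Constant signals yield no peaks (not an error);
  fewer than two mid-swing peaks, non-alternating events, all-zero Wilcoxon
  differences, and missing (subject, condition) cells raise named errors.
- **Known limitations.** The generator's independence of the two systems'
  timing draws means a trial's IMU and walkway records are statistically
  consistent but not sample-level identical, as two real devices on one
  walk would be; symmetry-ratio SDs are reproduced only approximately (the
  single bilateral correlation cannot match all three ratio SDs at once);
  and classification accuracies on synthetic cohorts should be read as
  qualitative, not quantitative, reproductions.
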