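---
title: "Methods: registration, health scores and ordinal grading of facial kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration, health scores and ordinal grading of facial kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hbgrade` grades mimetic-muscle function on the adjusted House–Brackmann
(HB) scale {1, 2, 3, 6} from 3D trajectories of 21 facial points of interest
(POI) recorded during standard facial exercises. This vignette is the
package's own account of the statistical procedure: the model at each stage,
its assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the method leaves room.

## Data model

A *session* is one clinic visit: up to nine exercise recordings, each a
variable-rate time series (seconds) of 21 POI in sensor-frame Cartesian
coordinates (meters) — 3 × 21 × 9 = 567 coordinate curves when complete.
Five exercises (Raising, Frowning, Smiling, Baring, Pursing) carry
indicators; the other four (Closing, Blowing, and the two combined
exercises) stay in the data model but are not analysed, because eye-region
and cheek tracking is too noisy to support stable indicators. Raw grades
4 and 5 are merged into 3 and 6 respectively: both are rare and clinically
close to their neighbours, and merging stabilises every later fit.

The on-disk dialect (one directory per session: `manifest.txt` plus a
64-column delimited trajectory file per exercise) is a repository
convention chosen to be self-describing and diff-able, not a claim about
any particular sensor's native format. Timestamps may be irregular; nothing
is resampled at ingest, because resampling is a registration concern.
Exclusion of outlier sessions is a human decision: the manifest carries an
`excluded` flag, and the only automation is a warning when a session's peak
absolute intensity lies beyond a robust z-score threshold (default 5,
median/MAD) of the cohort.

## Stage 1 — registration

Patients perform exercises at different times, speeds and repetition
counts, so all curves are first aligned to a common reference timeline.

**Alignment curve.** Per exercise one scalar curve that changes most during
the exercise: for Raising/Frowning the sum of the left (POI 4–2) and right
(POI 10–8) eyebrow-to-inner-eye-corner distances; for the mouth exercises
the mouth-corner distance (POI 14–15). Including both facial halves matters
because hemiparetic patients move only one side. The curve is smoothed by a
centered moving average (default window 5 samples; Savitzky–Golay optional)
and min-max normalized. For Frowning, Smiling and Pursing the natural
motion *decreases* the alignment distance, so the normalized curve shows
dips rather than bumps; the polarity is flipped automatically whenever the
resting start of the curve sits in the upper half of its range. This flip
is a package design choice — the alternative, per-exercise hard-coded
polarities, would break on atypical performances.

**Repetition detection.** The normalized curve is compared by dynamic time
warping (classic dynamic programming; diagonal/horizontal/vertical steps,
squared-difference local cost) against reference templates with k = 2, 3, 4
raised-cosine bumps of equal width, rests taking 20% of the span. The k
with minimal path-length-normalized ("average") distance wins; ties break
toward 3, the instructed count. The raised-cosine shape and the 20% rest
fraction are plausibility choices — smooth, compactly supported activation
is what cooperative patients produce; nothing downstream is sensitive to
the exact template shape because the comparison is scale-free and
path-normalized.

**Landmarks.** Begin/end times of each repetition are the crossings of an
activation threshold, default 0.15 of the normalized range, located within
the stretch of signal the DTW path maps onto each template bump. Two
robustness measures matter on low-amplitude curves (severe palsy): the
above-threshold run is grown outward from the bump window's peak (so a
single noise spike elsewhere cannot stretch the interval), and the
threshold is referenced to the *resting floor* — the median of the samples
the DTW path maps onto the template's rest regions — because min-max
normalization bottoms out at the deepest noise dip, which on
signal-to-noise-poor curves sits well below the true resting level. On
clean data the floor is 0 and the rule reduces to the plain 0.15 crossing.

**Warping.** The reference landmark times t_0j are the reference template's
own threshold crossings, so a session that performs exactly the template
maps onto itself. The warping function w(t_0j) = t_ij is a monotone
piecewise-cubic interpolant, extended linearly with the boundary slope
outside the knot range. We use the Hyman-filtered cubic spline
(`stats::splinefun(method = "hyman")`) rather than Fritsch–Carlson local
Hermite slopes: with only 2k landmark knots the FC secant-based slopes
carry an O(h²) error that visibly misaligns the steep bump flanks (about
2.3% RMS of range between two noiseless sessions with different speed
profiles), while the Hyman spline — whose slopes come from a C² fit, with a
monotonicity filter — brings this to about 0.4% and is equally guaranteed
to be strictly increasing, hence invertible, which is what a time warp must
be. All 63 coordinate curves of one exercise share the single warp derived
from its alignment curve, and are evaluated on a common grid of 100 points
on [0, 1] by linear interpolation between samples.

**Repetition selection.** The second repetition is analysed (first and last
are most often corrupted by start/end noise; with only two repetitions the
second is the last). The cut extends to the midpoints toward neighbouring
repetitions, keeping a rest margin on both sides.

## Stage 2 — indicator curves and health scores

Fourteen indicator curves per session (symmetry, intensity, speed for
Raising/`eyebrows`, Frowning/`frowning`, Smiling/`smiling`,
Baring/`teeth`; intensity and speed for Pursing/`lips`):

* **Symmetry** SI(t) = min(v_L, v_R) / max(v_L, v_R) of homologous
  left/right distances, in (0, 1], 1 iff both halves move identically.
  Raising/Frowning use inner-eyebrow-to-inner-eye-corner distances,
  Smiling/Baring mouth-corner-to-outer-eye-corner — eye corners because
  they are the most stable tracked points.
* **Intensity**: signed relative change against the resting baseline —
  1 − 1/max(v_L(t)/v_L(0), v_R(t)/v_R(0)) for Raising/Frowning/Smiling, the
  mouth-ellipse-area version for Baring (the π/4 constant cancels), and the
  corner-distance version for Pursing. Signs are kept: what carries grade
  information is distance from zero, and folding by absolute value would
  discard the direction of motion. The baseline v(·)(0) is the mean of the
  first 5 grid points of the selected repetition's rest margin (damping
  sensor noise); a strict first-sample mode is available to match the
  formulas literally.
* **Speed**: the warping function itself, reported in the
  sample-to-reference direction (the inverse of the registration map) and
  affinely rescaled to the unit square, so that a fast onset shows as a
  curve above the diagonal early on — the orientation in which "steep at
  the beginning" describes a fast, typically healthy, performance.

All indicators are ratios of distances, hence invariant under rigid
translation and uniform scaling of the coordinates.

**Health scores.** Each indicator label gets one scalar-on-function
logistic regression p = 1/(1 + exp(−α − ∫X(t)β(t)dt)), trained on the
extreme groups only — Healthy = adjusted HB1 vs Sick = adjusted HB6 — and
then applied to *every* session; the score is the fitted probability of
belonging to the Healthy group. β(t) is expanded in a B-spline basis
(default dimension 8 on the registered [0, 1] domain) and the integral is
computed by trapezoid quadrature on the common grid, which reduces the fit
to a penalized logistic regression on quadrature-weighted basis scores,
solved by damped IRLS. A small ridge penalty (default 1e-3 on the basis
coefficients, none on the intercept) is essential: with well-separated
extreme groups and a rich functional covariate, the unpenalized MLE
diverges under complete separation; the penalty keeps scores finite and
calibrated while leaving non-separated fits essentially untouched (a
dimension-1 basis with zero penalty reproduces ordinary scalar logistic
regression to optimizer precision). Speed curves enter as
warping-minus-identity residuals, removing the deterministic diagonal
trend that would otherwise dominate the integral; raw values are a
configuration switch.

Score–grade association diagnostics are Spearman rank correlations (with
t-approximation p-values) of each score against the clinician grades, and
the Pearson correlogram between scores (pairwise-complete observations).

## Stage 3 — ordinal classification

Health scores feed a proportional-odds model over the ordered adjusted
grades: P(HB ≤ j) = plogis(α_j + Σ_i β_i p_i), j ∈ {1, 2, 3}, with class
probabilities as differences of consecutive cumulative probabilities and
P(HB ≤ 6) = 1. The β_i are class-independent (proportional odds, exactly as
the cumulative-logit formulation states); thresholds are kept strictly
increasing by parametrizing the gaps on the log scale. Fitting maximizes
the weighted log-likelihood by BFGS with the analytic gradient
(convergence tolerance 1e-8, at most 500 iterations); the gradient is
verified against central finite differences in the test suite, and the
whole fit against an independent proportional-odds implementation.

**Weights.** Each session is weighted by the inverse frequency of its
class, so all classes carry equal total weight despite HB1 dominance.
Inside the fit, weights are rescaled to mean 1: this changes neither the
optimum nor any prediction (the likelihood is scale-invariant in the
weights), but keeps the AIC on the usual per-observation scale — with raw
inverse frequencies the weighted log-likelihood sums to the number of
classes and the 2·(#parameters) penalty would empty every stepwise
selection.

**Variable selection** is greedy bidirectional stepwise AIC from the empty
model: at each step the single add-or-drop move with the largest AIC
reduction is taken until no move improves. On identical data this
reproduces the selection of the standard stepwise machinery around the
reference proportional-odds implementation, move for move. Note the noise
admission of AIC stepwise is intrinsically stochastic — each pure-noise
candidate clears the AIC bar with roughly the χ²₁ > 2 tail probability of
0.16 — so the package's selection tests check behaviour across replicated
draws rather than a single realization.

**Evaluation** is the confusion matrix over the adjusted grades (rows =
clinician) and per-class/overall rates of *correct* and *approximate*
classification, the latter meaning |predicted − true| ≤ 1 on the numeric
grade values — so predicting 6 for a true 3 (distance 3) is not
approximate. Exact fractions are kept; display rounds to integer percent.
Ties in the argmax prediction break toward the lower (healthier) grade.

## The synthetic cohort generator

Clinical recordings are restricted, so validation rests on a generator
(`simulate_session()`, `simulate_cohort()`) that emulates the statistical
structure the pipeline assumes:

* a bilaterally symmetric 21-POI neutral face template (meters, plausible
  adult anthropometry);
* per indicator exercise, rest − k raised-cosine activation bumps − rest
  (k ∈ {2, 3, 4}), with each measured POI pair displaced along its
  separation vector so the alignment distances respond linearly to the
  activation — this makes repetition boundaries well defined, and the
  generator's ground-truth landmark times are the activation's crossings of
  the 15% threshold, the same definition the extractor uses;
* grade-dependent severity: attenuation of the affected side
  (1.0/0.8/0.5/0.05 for grades 1/2/3/6), global range-of-motion scale
  (1.0/0.9/0.7/0.4), and a one-parameter monotone power distortion of
  normalized time, u ↦ u^γ with γ = 0.75/0.90/1.05/1.25 — fast onset for
  healthy performers, slow for severe palsy. Cohorts add mild within-grade
  log-normal jitter to these. All severity values are plausibility choices
  reproducing the qualitative contrasts reported for real patients
  (symmetry near 1, larger range of motion and faster onset for HB1); the
  real per-grade amplitude and velocity distributions are unpublished.
* a per-session sampling rate drawn from 12–30 Hz with ±10% timestamp
  jitter (variable-rate depth-sensor tracking), and i.i.d. Gaussian noise
  of 0.5 mm per coordinate. Baring on the severely affected side is then
  genuinely low-SNR (≈3:1 after smoothing) — deliberately so, as this is
  the regime real systems report as hardest.

What the generator does **not** emulate: synkinesis (involuntary
co-contraction), the face tracker's own symmetry bias (appearance-model
trackers trained on healthy faces tend to place points more symmetrically
than the true anatomy, flattering severe palsy), autocorrelated or
heteroscedastic sensor noise (an optional switch exists for robustness
experiments), and photorealistic geometry. Passing tests therefore show
the *pipeline* is correct and robust at realistic noise levels, not that
real clinical accuracy will match synthetic accuracy: synthetic grade
separation is cleaner than clinical grading, which contains subjective
judgment, so in-sample synthetic accuracy (≈100%) exceeds what the same
procedure reports on real data (≈60% correct, 86% approximate).

## Numerical choices and degenerate inputs

* Monotone warp interpolation: Hyman-filtered cubic spline (see above);
  linear extension with boundary slopes outside the knots, clamped to the
  recording span when evaluating positions.
* DTW on min-max-normalized curves; distances path-length-normalized
  before template comparison; detection ties toward 3.
* Landmark threshold 0.15 of range, floor-referenced on noisy curves;
  adjacent above-threshold runs that touch are clipped at their midpoint.
* Flat (numerically constant) alignment curves raise a distinct
  `flat_signal` error; degenerate geometry (zero distances), one-class
  training sets, grid mismatches and missing upstream artifacts each raise
  their own named condition rather than a generic failure.
* IRLS with step-halving for the penalized functional logistic fit
  (objective tolerance 1e-10); complete separation is detected (|η| > 25)
  and reported, with a warning only when the penalty is zero.
* The proportional-odds optimizer initializes thresholds at weighted
  empirical cumulative logits.
* Deterministic text output (12 significant digits) in every pipeline
  artifact, so identical seeds and configurations give byte-identical
  tables.

## Problem sizes

The test suite validates registration recovery on 30 noiseless sessions
(100% repetition detection; landmark error below one sampling interval)
and 50 default-noise sessions (≥90% detection), parameter recovery of the
ordinal model at n = 500 over 20 replicates and of β(t) at n = 400 over 20
replicates, and the full pipeline on cohorts of 30–122 sessions mirroring
the clinical cohort's 58/21/23/20 grade mix. These sizes are the package's
validation design: large enough for stable statistics at the cohort scale
the method targets.

## Limitations

Indicator-bearing exercises are five of nine; eye-closure and cheek
exercises await a less noisy tracker. One warp per exercise assumes the
whole face follows the alignment curve's timing. The health-score stage
assumes extreme groups are available for training (at least 3 sessions per
group per indicator). Stepwise AIC on near-separable synthetic scores often
keeps a single dominant score — informative about the synthetic geometry,
not about which indicators matter clinically. Cross-validated model
assessment and non-parametric classifiers are out of scope.
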