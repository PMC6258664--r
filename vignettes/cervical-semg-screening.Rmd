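---
title: "Screening for cervical spondylosis from multichannel neck surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for cervical spondylosis from multichannel neck surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Cervical spondylosis (CS) is a degenerative disorder of the cervical spine.
Its muscular signature is accessible non-invasively: surface
electromyography (sEMG) of the neck shows altered paraspinal activation in
patients, most famously a loss of the *flexion-relaxation* phenomenon — in
healthy people the cervical erector spinae fall nearly silent at full neck
flexion, while in patients they keep firing.

`cervemg` implements a complete screening pipeline over six-channel neck
sEMG recorded during seven standardized movements (A1 bow, A2 head
backwards, A3/A4 left/right flexion, A5/A6 left/right rotation, A7 hands
up), with muscles M1/M6 = left/right sternocleidomastoid, M2/M5 =
left/right upper trapezius, M3/M4 = left/right cervical erector spinae:

1. **Feature extraction** — a fixed 2949-dimensional feature vector per
   sample (423 from A1, 421 from each other movement).
2. **Feature selection** — an iterative random-forest top-25 union
   algorithm over 7 subject-grouped data subsets.
3. **Classification** — gradient-boosted regression trees (GBRT) with
   binary logistic loss, written from first principles.
4. **Evaluation** — subject-grouped 16:4:5 train/validation/test splitting,
   subject-grouped 5-fold cross-validation, confusion-matrix metrics
   (accuracy, sensitivity, specificity, FNR, FPR) and ROC-AUC.

Because clinical sEMG recordings of this kind are not publicly available,
the package ships a synthetic cohort simulator so that every stage is
exercised end to end on data with known ground truth.

## The feature schema

Each sample is one acquisition session: 7 movements x 6 synchronized
channels. Per channel, 63 features are extracted:

* **TF (11, time domain)**: IEMG, AEMG/MAV, RMS, variance, waveform length,
  zero crossings, slope-sign changes, Willison amplitude, log detector,
  skewness, kurtosis. The Willison threshold is 0.01 SD of the channel.
* **FF (14, frequency domain)**: from a Hann/50%-overlap Welch PSD —
  median frequency, mean power frequency, peak frequency, total power,
  absolute spectral moments 1–3, low/high band ratio (20–150 vs 150–450
  Hz), power share within ±10 Hz of the peak, variance of central
  frequency, four absolute band powers (20–50, 50–100, 100–150, 150–450 Hz).
* **WL + WLP (7 + 16, time–frequency)**: db4 4-level discrete-wavelet
  subband energies (D1–D4, A4), their total, the Shannon entropy of the
  relative subband energies; absolute and relative energies of the 8
  terminal nodes of a 3-level db4 wavelet-packet tree.
* **AR (14)**: the coefficients of one order-14 Burg autoregressive model
  (so the printed count of 14 equals one coefficient vector).
* **EY (1)**: sample entropy (m = 2, r = 0.2 SD, Chebyshev distance,
  self-matches excluded).

Per movement, 43 features are extracted (plus 2 FRR values for A1 only):

* **FRR (2, A1 only)**: for each cervical erector spinae channel, the peak
  motion-phase RMS envelope divided by the mean hold-phase envelope, with
  the recording split into motion/hold/motion thirds.
* **DU (7)**: per-channel activation duration (envelope above 20% of its
  95th percentile) and the any-channel active duration.
* **ACI (15)**: Pearson co-activation of the RMS envelopes of all channel
  pairs.
* **UN (9)**: channel shares of movement energy, their normalized entropy,
  coefficient of variation, and maximum.
* **SYM (12)**: RMS ratio, median-frequency ratio, zero-lag envelope
  cross-correlation and energy-difference index for the three left/right
  muscle pairs.

The arithmetic closes exactly: 423 = 2 + 43 + 6x63 for A1, 421 = 43 + 6x63
for A2–A7 (the FRR pair exists only for the bow), 2949 in total, 11 feature
families. The movement-level families are fixed by name, count and
semantics; the DU/ACI/UN/SYM formulas above are this package's
concretization, kept behind the family interface so a different allocation
can replace them without touching callers.

Numerical conventions worth knowing: wavelet analysis truncates to the
largest multiple of 16 so the periodized transform is exactly orthogonal
(Parseval holds to machine precision); sample entropy counts matches over
all m-templates and all (m+1)-templates, which makes it exactly invariant
under time reversal, returns 0 for constant input and caps at log(N-m)
when a count is empty; sample entropy of long channels is computed on a
central 2000-sample analysis window, the usual practice for a quadratic
cost statistic; constant-signal skewness/kurtosis are defined as 0; the
log detector floors |x| at 1e-300; spectral features exclude DC and error
on an all-zero signal rather than emitting NaN.

## Missing data

Feature cells may be missing. At training time, imputation is
class-conditional: missing CS cells receive the CS column mean, healthy
cells the healthy mean. At inference time labels are unknown, so held-out
data receive the *training set's* global column means. Observed cells are
never altered. (Class-conditional imputation uses labels by construction;
applying it to test data would leak them, hence the global-mean rule
outside training.)

## Feature selection: iterative forest-union

The selection algorithm (`rf_union_select()`) divides the samples into 7
disjoint, subject-grouped, class-stratified subsets. On each subset it
iterates: fit a random forest whose tree count grows with the iteration
(50 + 25t by default), take the 25 most impurity-important features, union
them into the subset's running set; stop when the set has not grown for 5
consecutive iterations (or at 100 iterations). The final feature set is the
union over subsets. Design choices the source left open, decided here:

* Subsets are disjoint partitions rather than bootstraps — disjointness
  maximizes the diversity the final union benefits from.
* The tree schedule is the simple deterministic ramp above; any function of
  the iteration index can be supplied.
* Stopping uses a patience window because a literal "did not grow this
  iteration" test would stop spuriously early under forest randomness.
* Importance is mean impurity decrease (the conventional, cheap choice);
  permutation importance was rejected for cost.

The per-subset traces are non-decreasing by construction and saturate; on
planted-signal simulations the union reliably recovers informative features
(asserted in the test suite: at least 4 of 5 planted features from 1000
columns at n = 300).

## The classifier

`gbrt_fit()` is a from-scratch gradient-boosted regression-tree binary
classifier. With log-odds scores $\hat y$ and logistic loss
$l(y,\hat y) = y\log(1+e^{-\hat y}) + (1-y)\log(1+e^{\hat y})$, each stage
adds the tree minimizing the second-order approximation of the regularized
objective: for a leaf with gradient sums $G = \sum g_i$, $H = \sum h_i$
($g_i = p_i - y_i$, $h_i = p_i(1-p_i)$) the optimal weight is
$-G/(H+\lambda)$ and a split's gain is
$\tfrac12\left[\frac{G_L^2}{H_L+\lambda} + \frac{G_R^2}{H_R+\lambda}
 - \frac{G^2}{H+\lambda}\right] - \gamma$,
with complexity penalty $\gamma$ per leaf plus $\tfrac\lambda2\sum w^2$.
Split search is exact greedy over midpoints of consecutive distinct sorted
values (ties resolved to the lowest feature index, then lowest threshold),
the initial score is the training-prevalence log-odds, and defaults are
learning rate 0.1, depth 3, $\lambda = 1$, $\gamma = 0$. Training is fully
deterministic (no subsampling), training log-loss is recorded per stage and
is non-increasing at small learning rates, and `gbrt_tune_trees()` picks
the tree-count prefix maximizing validation AUC. The split kernel is
validated in the tests against an exhaustive R-level search, and a depth
argument of 1 reproduces the classic additive-model limits (XOR is
unreachable).

## Evaluation protocol

All splitting is grouped by subject: the three repetitions of one volunteer
never straddle a boundary, for the 16:4:5 train/validation/test split
(largest-remainder allocation per class) and for the 5-fold
cross-validation alike. Inside each CV fold, imputation statistics, feature
selection and the classifier are derived on the training part only:
selecting features once on all data before cross-validating would leak the
test folds, so selection is re-run per fold. AUC follows the standard ROC
convention (trapezoidal; ties at half credit), delegated to pROC and
cross-checked in the tests against exhaustive concordant-pair counting. The
Pearson label screen reports raw two-sided p-values at the conventional
p <= 0.05 rule with no multiplicity correction; the significant-feature
count on any cohort is therefore descriptive, not inferential.

`aggregate_muscle_movement()` reproduces the heat-map view of which
muscle-movement pairs drive the decision: counts of selected channel-scope
features and summed split-gain importance per (movement, muscle) cell, with
movement-scope features as per-movement marginals.

## The synthetic cohort simulator

Each channel is zero-mean Gaussian noise shaped by a 4th-order Butterworth
band-pass (20–450 Hz at the default 1 kHz sampling rate; the upper edge
adapts to 0.45 fs for low-rate configurations), amplitude-modulated by a
movement envelope: trapezoidal rise–hold–fall for A2–A7, and a
motion/hold/motion three-phase profile for A1 so the flexion-relaxation
ratio is meaningful (healthy erector-spinae hold level 0.3 of the motion
amplitude; other muscles 0.7).

Class effects are deliberately confined to the muscle–movement pairs most
implicated in the disorder — the cervical erector spinae during the bow
(A1 x M3/M4) and the upper trapezius during hands-up (A7 x M2/M5):

* loss of hold-phase suppression (FRR multiplier 0.55 at effect size 1),
* amplitude elevation (gain 1.4),
* spectral compression (factor 0.85, a downward shift of the spectral
  center).

All multipliers scale as `m^effect_size`, so `effect_size = 0` is *exactly*
the null — both classes are draws from one process — and effects grow
smoothly with the dial. These magnitudes are simulator defaults chosen to
be physiologically plausible in direction (reduced flexion-relaxation and
elevated trapezius activity are reported pathology markers), not clinical
claims; the simulator emulates band-limited stochastic structure, phase
envelopes, repetitions and missingness (MCAR over feature cells), but not
motor-unit microstructure, electrode artifacts, or between-subject
anatomical variability. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted effects, not clinical
performance on real patients; clinical cohorts of this kind are private,
and no clinical performance figure is a target of this package.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline on cohorts
of 30 + 30 subjects x 3 repetitions at the simulator defaults (1 kHz, 5 s
per movement) — 180 samples x 2949 features — with selection patience 3 and
iteration cap 25, and 80 boosting trees; these sizes were chosen as the
smallest at which the grouped-CV recovery behavior is stable. Unit tests
use reduced sampling rates (200–500 Hz) and shorter recordings where only
structural contracts are exercised; the statistical contracts (null
exchangeability, effect monotonicity, planted-feature recovery) always
state their cohort sizes inline.

## Known limitations

* The 43 movement-level feature formulas are one count-faithful
  concretization among several defensible ones.
* The simulator's class-effect magnitudes are placeholders with plausible
  direction; only their recoverability, monotonicity and exact-null
  behavior are asserted.
* Binary classification only; no probability calibration beyond the
  logistic link; no histogram split approximation, so very wide tables at
  large n will be slower than production boosting libraries.
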