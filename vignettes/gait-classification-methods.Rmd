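---
title: "Methods: gait-based classification of diabetic neuropathy and foot-ulcer history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-based classification of diabetic neuropathy and foot-ulcer history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diabetic neuropathy (DN) alters lower-limb biomechanics during walking, and
a history of diabetic foot ulceration (DFU) marks a more advanced stage of
the same process. Two signal families carry this information during gait:
surface EMG of the gastrocnemius lateralis (GL), vastus lateralis (VL) and
tibialis anterior (TA), and the three components of the ground reaction
force (GRF), of which the vertical component (vGRF) shows the classic
two-hump "M" shape over one stance. The clinical literature reports two
robust group effects: a *later muscle-activation peak* and a *lower second
vGRF hump* (weaker push-off) in DN and DFU patients. Individual raw signals
are too variable for manual reading, which motivates a machine-learning
pipeline: condition the signals, extract fixed feature banks, rank and
prune the features, and classify each gait cycle with a tuned k-nearest-
neighbour (KNN) model under subject-wise cross-validation.

`gaitdx` implements that pipeline end to end, together with a synthetic
cohort generator that reproduces the statistical structure the analysis
assumes, so every stage is testable without access to clinical recordings.

## Synthetic cohort

`cohort_config()` defaults encode the study conditions: 21 subjects
(control n = 6, DN n = 6, DFU n = 9), 20 gait cycles per subject, sampled
at 1000 Hz with a 0.8 s stance. The class effects are

* an activation-peak delay of 60 ms (DN) and 100 ms (DFU): the EMG envelope
  is a Gaussian bump centred at 40% of the cycle for controls, shifted
  later by the class delay plus a subject-level gait-timing effect;
* a 15% reduction of the second vGRF hump for both diseased classes;
* the same gait-timing delay applied to the second (push-off) vGRF hump and
  the propulsion hump of the anterior-posterior shear.

The last point is a deliberate modelling decision. The 19 time-domain EMG
features are amplitude statistics and are mathematically invariant to a
pure time shift of the activation envelope, so a delay expressed *only* in
the EMG would be invisible to the downstream feature banks, and DN versus
DFU would be undecidable from any of the extracted features.
Physiologically the two effects are coupled anyway: the plantar flexors
drive push-off, so delayed activation delays propulsion, which is exactly a
later second vGRF hump. The coupling reuses the configured delay and adds
no free parameter. A useful corollary that the package's own experiments
make visible: EMG-only configurations hover near chance on this generator,
because amplitude statistics cannot see a timing shift — a caution that
transfers to real studies relying on time-blind feature banks.

Other generator choices, fixed once:

* EMG carrier: white noise band-passed 25–499 Hz (unit SD), so the
  preprocessing chain is non-degenerate; additive noise at `noise_sd`
  (default 5% of the nominal amplitude) on every channel.
* vGRF: two Gaussian humps (centres 27% and 72% of stance, SD 13% of
  stance) multiplied by a quarter-power sine taper that forces exact zeros
  at foot contact and toe-off; each hump is rescaled so its *tapered*
  maximum equals the target height, which makes the configured second-peak
  reduction exact by construction. The inter-hump valley sits near 45% of
  the peak, safely above the 5% segmentation threshold, so every cycle
  yields exactly one stance interval.
* Subject random effects: a gait-timing shift shared by all of a subject's
  cycles (`subject_sd`, default 10 ms) and a log-normal amplitude factor
  (sdlog 0.1). These induce the within-subject correlation that makes
  subject-wise cross-validation strictly harder than record-wise — the
  property the leakage experiment quantifies.
* 20 cycles per subject: a free parameter of the emulated study; 20 gives
  420 records, enough for balanced 5-fold subject-wise CV at desk scale.

What the generator does *not* emulate: kinematics, plantar pressure,
electrode-placement variability, non-stationary fatigue effects, or any
within-trial autocorrelation between consecutive cycles. Passing tests on
this cohort therefore demonstrate the pipeline's correctness and its
statistical discipline, not clinical performance on real recordings.

## Signal conditioning

EMG: full-wave rectification, then a fourth-order Butterworth band-pass
25–499 Hz, then 60 Hz notches (quality factor 30) at every harmonic below
Nyquist — in that order. GRF: fourth-order Butterworth low-pass at 100 Hz.
All filters are zero-phase. The zero-phase operator is realized as the
squared-magnitude response of the designed IIR cascade applied in the
frequency domain to an even (mirror) extension of the signal: this is the
forward–backward (filtfilt) operator with the boundary transients removed,
it has exactly zero phase, and it commutes with time reversal to floating-
point precision. The effective attenuation is the square of the design
magnitude. The notch bandwidth is a choice (Q = 30); the band corners are
part of the method definition.

Gait cycles are segmented from the conditioned vGRF as maximal runs above
5% of the per-recording maximum sustained for at least 50 ms; intervals are
0-based, half-open `[start, end)`. "Gait cycle" is operationalized as the
stance captured by the force plate, since the vGRF is zero off-plate. A
quality screen stands in for the semi-manual curation a human rater would
do: accept a stance iff its duration lies in 0.3–1.5 s and its peak is
positive.

Scale normalization: the vGRF (strictly positive) is divided by its
segment mean, so the result has mean exactly 1. Band-passed EMG and the
shear GRF components integrate to (near) zero, so dividing by the raw mean
is ill-posed; those channels are divided by their mean absolute value
instead, which removes amplitude scale while preserving sign structure.
One consequence, accepted deliberately: on mean-abs-normalized EMG the
LMAV feature (log of the mean absolute value) is identically 0. It stays
in the bank because the 19-feature contract is fixed; the zero-variance
flag in the pruning report marks it. Normalization is per segment, not per
trial.

## Feature banks

**EMG (19 per muscle):** LMAV, NSV, waveform length, Wilson amplitude,
slope-sign changes, zero crossings, Hjorth mobility and complexity,
skewness, four Yule–Walker AR coefficients, the even time-domain spectral-
moment surrogates m0/m2/m4/m6, and the mean absolute first and second
differences (AC1, AC2). Where several variants of a definition circulate,
the registered defaults are: natural log for LMAV; the v-order statistic
with v = 3 for NSV; `sum(diff^k(x)^2)` for the moments; thresholds
θ_wamp = 0.05 (on normalized signals), θ_zc = θ_ssc = 0; population
(biased) skewness; Yule–Walker AR estimation. Each is a single registry
entry that can be swapped without touching callers.

**GRF (195 per component):** 50 time-domain features (the 19 above, with
AR falling back to 0 on degenerate constant segments, plus 31 registered
amplitude/shape/timing statistics — extrema, principal-peak heights and
times, dispersion and percentile statistics, slope statistics, crest/
shape/impulse factors); 24 frequency-domain features from a one-sided
Hann-window periodogram with the DC bin excluded (peak/mean/median
frequency, spread, skewness, kurtosis, normalized entropy, flatness, band
fractions, rolloffs, spectral slope and crest); and 121 time-frequency
features from an 8-level discrete wavelet transform. Peak times are
fractions of segment length so variable-length stances are comparable.

The DWT uses db4 (the standard biosignal default) in the periodized
orthonormal construction, which gives exact perfect reconstruction and an
exact energy partition across D1–D8 + cA8 — the two invariants the test
suite asserts. Segments are symmetric-reflect padded to the next multiple
of 2^8 before the transform. Thirteen named bands feed the feature
registry: D1–D8, their concatenation cD, the approximation signals A6–A8
reconstructed to signal length, and the level-8 approximation coefficients
cA8. Nine statistics per band plus four global features give
9 × 13 + 4 = 121. The exact composition of the 50/24/121 registries is a
reconstruction constrained by the printed counts and the published band
list; the registries are the single source of truth and deliberately
swappable.

## Selection and classification

Correlation pruning scans column pairs in input order and drops the later
member of any pair with |Pearson r| > 0.9; zero-variance columns are kept
and flagged. Pruning runs *before* ranking by default, so collinear
duplicates cannot distort the rankers (`run_pipeline(prune_first = FALSE)`
reverses the order for comparison; the two orders are genuinely different
pipelines and both are supported because the method description admits
either reading).

Four filter-type rankers are implemented from first principles (no
pre-installed R package provides them): chi-square on 10 equal-frequency
bins; greedy mRMR under the MID criterion with binned mutual information;
multi-class ReliefF (k = 10 hits/misses, Manhattan distances on
range-normalized features, miss terms weighted by class priors); and NCA
feature selection — nonnegative per-feature weights learned by projected
full-batch gradient ascent on the soft leave-one-out nearest-neighbour
accuracy with an L2 penalty (λ = 1/n by default, features standardized
internally, log-sum-exp stabilized softmax, adaptive step halving, 100
iterations). Ties everywhere break by input column order. The mRMR scores
are the greedy criterion values at each step and are not forced monotone;
the three sort-based rankers produce monotone non-increasing scores.

Classification is per gait-cycle record. Each CV fold standardizes
features on its training records, balances the training classes to the
majority count with SMOTE (synthetic points drawn on segments between
same-class nearest neighbours; never applied to test records), and
predicts held-out records with the distance-weighted KNN. The shipped
default — 1 neighbour, Euclidean distance, squared-inverse weighting — is
the tuned optimum; `tune_knn()` re-derives it by deterministic grid search
over k ∈ {1,3,5,7,9}, {euclidean, cityblock}, {uniform, inverse,
squared-inverse}. With k = 1 the weighting is inert for prediction, so ROC
scores at k = 1 are built from the distance to the nearest training point
of each class (normalized squared-inverse), keeping the ROC non-degenerate.

Folds are subject-wise: subjects are shuffled within class and dealt
round-robin, so all records of a subject land on one side of every split.
A machine-checked assertion refuses any configuration that claims
subject-wise validation while splitting a subject. `record_wise_folds()`
is provided solely to measure the identity-confounding inflation that
subject-wise splitting prevents.

The incremental forward search evaluates the top-1, top-2, … top-k ranked
features and reports the smallest k attaining maximal pooled accuracy.
Metrics pool held-out predictions across folds into one confusion matrix
(per-fold averaging is available via the per-fold predictions); accuracy,
macro precision, macro sensitivity and macro F1 are reported as
percentages, with macro one-vs-rest AUC by the rank (Mann–Whitney) form.

## Calibration, problem sizes, and known limitations

Feature ranking sees the whole table before cross-validation — faithful to
the original methodology, but it means selection leakage: under a null
cohort (all class effects zero) the pipeline's own CV accuracy sits about
10 points above chance because the ranker has cherry-picked sample noise.
The test suite therefore calibrates chance level on an *independently
generated* cohort, with features and depth frozen on the first cohort:
held-out accuracy is then statistically indistinguishable from the 33.3%
chance level, while the strong-effect configuration keeps ≥ 90% accuracy
out of sample. The same protocol is used in `scripts/acceptance.R`.

Problem sizes used by the tests and the acceptance script, chosen as
desk-scale study conditions: the full 21 × 20-cycle cohort for the
strong-effect runs; 21 × 8-cycle cohorts for the 20-seed null-calibration
and leakage experiments; 50 seeded repeats for the planted-feature ranking
checks; Monte-Carlo generator checks at 200 cycles per class with 2-SE
tolerances.

Known limitations: the feature registries are reconstructions (printed
counts and band lists constrain them, but not every individual formula);
the generator's class effects are low-dimensional caricatures of real
gait pathology; EMG-only configurations are near chance by construction
(see above); and with 21 subjects the between-seed variance of any
subject-wise CV estimate is large — single-seed accuracies should be read
with that in mind.
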