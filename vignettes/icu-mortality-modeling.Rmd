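---
title: "Modeling ICU mortality from clinical trajectories and note text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ICU mortality from clinical trajectories and note text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icutraj)
```

## The problem and the modeling approach

Severity-of-illness scores for intensive care traditionally summarize a
patient's first 24 hours by the *single most abnormal* value of each
laboratory test and vital sign, and ignore clinical notes entirely. This
package implements, and makes testable end to end, the alternative: use
*every* recorded observation of each variable to characterize the
patient's clinical trajectory, add the free-text vocabulary of the first
day's notes, and feed both into a penalized logistic model of in-hospital
death.

Three nested model families are built from the same cohort:

1. **baseline** — per variable, the minimum and maximum value in the
   24-hour window (2V predictors for V variables); a surrogate for
   worst-value scores.
2. **trajectory** — per variable, eight summary measures: minimum,
   maximum, mean, sample SD, first value, last value, last-minus-first
   difference, and the least-squares slope in units per hour (8V
   predictors).
3. **trajectory + NLP** — the trajectory measures plus sublinear TF-IDF
   weights over the k most frequent note terms (8V + k predictors).

With the default 24-variable set and k = 1000, the three design matrices
have 48, 192 and 1192 columns.

All predictors enter linearly. The model is logistic regression with an L2
(ridge) penalty: we maximize

    l(b0, b) - (lambda / 2) * ||b||^2

with the intercept unpenalized, by iteratively reweighted least squares
(Newton steps with step-halving, which makes the penalized objective
nondecreasing). Predictors are z-standardized jointly before fitting so
the single penalty acts on one coherent scale; predictions are therefore
invariant to affine rescaling of any input column.

## Feature engineering choices

**The eight trajectory measures.** The set {min, max, mean, SD, first,
last, last−first, slope} is fixed by two constraints: the trajectory model
must have exactly 8 columns per variable, and the analyses the harness
reports (slopes per hour, first-to-last differences) must be among them.
The remaining measures are the standard distribution and variability
summaries a practitioner would reach for.

**Degenerate trajectories.** A patient with a single observation of a
variable has a well-defined min/max/mean/first/last but no defensible SD,
difference, or slope; these are treated as *missing*, not zero — zero
would assert "no change" without evidence — and are then median-imputed.
A slope is additionally treated as missing when the patient's
observations span less than one hour. The least-squares slope divides
measurement noise by the squared time spread, so two measurements minutes
apart yield slope estimates with Cauchy-like tails that say nothing about
a 24-hour trend; requiring a one-hour span keeps every slope an actual
trend estimate and makes group-mean summaries of slopes converge. (The
`ls_slope` primitive itself stays pure: it returns a value whenever two
points with distinct times exist.)

**Median imputation.** Missing measures are filled with the median
nonmissing value of that measure *among training patients only*; the
medians are stored in the fitted object and reused verbatim on test data.
The same train-only discipline applies to the vocabulary, the IDF
weights, the standardization constants and the selected penalty; the test
suite verifies all of these are bit-identical under arbitrary mutation of
held-out rows.

**Tokenization and TF-IDF.** Tokens are lowercased maximal alphanumeric
runs; single words only, no stemming, stop words or negation handling.
Each patient's first-24-hour notes are pooled into one note set. The
vocabulary keeps the k terms with the highest total training token count
(ties broken lexicographically; whether "most frequent" means token count
or document count is a genuine ambiguity — token count is the documented
choice). The weight of term j in a note set with term frequency tf is

    w = (1 + ln tf) * idf,   idf = ln((1 + N) / (1 + df)) + 1

with N training note sets and df the term's training document frequency.
The sublinear (logarithmic) term frequency makes copy-pasted repetitions
yield diminishing returns; the smoothed "+1" IDF dialect keeps every
vocabulary term usable (idf > 0) even when its df equals N. The natural
logarithm is a free choice — the base only rescales columns and is
absorbed by standardization. Vectors are deliberately *not*
length-normalized, so that text and structured predictors share one
z-standardized scale under the single ridge penalty.

## Penalty selection and validation design

The penalty is chosen on each training partition by stratified inner
cross-validation (default 5 folds, 7 log-spaced candidates from 1e-3 to
1e3), maximizing mean validation AUC; exact ties go to the larger
penalty. An optional one-standard-error rule (`one_se = TRUE`) picks the
largest penalty within one SE of the best, trading a little discrimination
for stability. AUC is used as the selection metric because it is the
metric the harness reports.

The harness mirrors the two validation strategies of multi-site clinical
model studies:

- **Pooled repeated nested CV**: R repetitions of stratified K-fold
  cross-validation (default 100 x 10, yielding 1000 fold AUCs per model
  mode). Every fit-time artifact is refitted inside each outer training
  partition. The discrimination estimate is the mean fold AUC with a
  percentile-bootstrap CI (default B = 1000) over the fold values; two
  models differ significantly when each one's 95% CI excludes the other's
  point estimate. Calibration (modified Hosmer-Lemeshow), AUPRC and the
  optimal cut point are computed on the pooled out-of-fold predictions of
  the first repetition, where each patient is predicted exactly once.
- **Cross-site transfer**: for every ordered pair of sites, a model fitted
  entirely on one site (including its own vocabulary and IDF) is scored on
  another. Out-of-vocabulary tokens at the test site contribute nothing —
  the structural property that makes transfer of text models meaningful.
- **Alive-at-24-hours sensitivity analysis**: drops patients who died
  inside the observation window (their observation and note streams stop
  at death, which could teach the model peri-death documentation) and
  reruns the nested CV.

Folds are stratified by outcome: at ~10% prevalence, unstratified 10-fold
splits of small cohorts would regularly produce single-class test folds.
Repetition r derives its fold seed from the master seed by a fixed
counter scheme, so the entire harness output is reproducible from one
integer.

**Calibration test.** The modified Hosmer-Lemeshow statistic splits
patients into G equal-count risk groups (default 10; boundary ties go to
the lower group, a documented convention) and computes
C = sum (O - E)^2 / (E (1 - E/n)), referred to chi-square with G − 2
degrees of freedom — the classical reference for a model estimated on the
same data. Groups with degenerate expected counts are merged into a
neighbor with a warning. The test suite checks the type-I error of this
reference directly: over 500 simulated cohorts of n = 5000 with a
correctly specified logistic model fitted per replicate, the rejection
rate at alpha = 0.05 must lie within 3 binomial SEs of 0.05.

**AUPRC** uses the average-precision step form rather than trapezoidal
interpolation (interpolating between PR points overstates the area); its
chance level equals the outcome prevalence. The **optimal cut point**
maximizes Youden's J by default (the criterion behind published
sensitivity/PPV pairs is rarely stated; F1 is offered as an alternative).
**Model comparisons** on fold AUCs use Welch's unequal-variance t test,
since fold-AUC dispersion differs between models.

## What the synthetic cohort generator emulates

The generator exists so that every downstream stage is testable without
access to any real EHR. It draws, per patient: a site (3 sites with
mixture weights 0.40/0.25/0.35), demographics and ICU type with realistic
case-mix proportions, an in-hospital death indicator at 10.4% prevalence
(site-scaled, renormalized so the marginal is exact), and for 14.7% of
decedents a death time inside the first 24 hours, uniform on 4-24 h.
Observation times per variable are a homogeneous Poisson process on the
patient's window — the simplest process producing irregular spacing —
truncated at death for early decedents; values follow
`baseline + trend * t + noise` with outcome-dependent baselines and
trends. Note-set token counts are multinomial over a configured term list
with outcome log-odds shifts and per-site weight boosts.

Outcome-dependent parameters held at their published values: the Glasgow
Coma Scale trend is +0.124 points/h for survivors vs −0.034 for
nonsurvivors (eye +0.031/−0.012, verbal +0.049/−0.016, motor
+0.043/−0.002), and the chemistry-panel last-minus-first differences
(bilirubin, urea, sodium, potassium, lactate) are encoded as trend =
difference / 24 h, since the generator is parameterized per hour.
Blood-gas variables and lactate carry much higher whole-variable
missingness (0.55-0.60) than routine labs and vitals, as in real ICU
extracts. Term-frequency shifts follow the published directionality:
terms of acute decompensation (*pupils*, *fixed*, *gag*, *ecmo*,
*sepsis*, *shock*, ...) are more frequent among decedents, surgical-status
and reassuring-examination terms (*pod*, *ebl*, *extubated*, *awake*,
*alert*, *denies*, *perrl*, ...) among survivors.

Free parameters — per-variable sampling rates, noise SDs, nonsurvivor
baseline shifts, note length (~120 tokens over 1-5 notes), the Zipf
background vocabulary (~1520 terms) — are fixed defaults chosen so that
the three model families land in a realistic discrimination range and in
the expected order (baseline < trajectory < trajectory+NLP, roughly
0.87/0.93/0.99 pooled AUC at n = 5000). Nonsurvivor baseline shifts are
~0.15-0.3 SD per variable; GCS noise SDs (1.2-2.2 points) make per-patient
slopes informative but far from deterministic.

The generator deliberately does **not** emulate: inter-variable
correlation (each variable is drawn independently), nonlinear or
non-monotone physiology, note grammar (notes are bags of tokens), charting
artifacts, or unit-system differences between sites. Passing tests
therefore demonstrate the *pipeline's* correctness and the *statistical*
properties of the methods — leakage-freedom, calibration of the tests,
recovery of configured effects, the ordering of model families under
genuine signal — not clinical performance on real data.

## Numerical and convention choices

- The observation window is half-open, [0, 24): an event at exactly 24 h
  belongs to the next day. Whether the original cohort rule was inclusive
  is unknowable; half-open avoids double counting.
- A stay of exactly 4 hours is eligible ("at least 4 hours" is read as
  inclusive); "first ICU admission" is encoded by an admission-rank column
  rather than recomputed from timestamps.
- Sample (n−1) SD throughout.
- IRLS converges when the max-norm of the penalized gradient falls below
  `tol` (default 1e-6); the fitted object carries the gradient norm as an
  optimality certificate. Step-halving guarantees monotone ascent; a
  near-singular Newton system falls back to a slightly ridged solve.
- Physiologic range truncation is off by default: clamping values at
  range limits would bias per-patient slope means away from the configured
  trends, destroying honest trend-recovery checks.
- Generated cohorts satisfy the eligibility rules by construction (adults,
  first admissions, stays >= 4 h), mirroring a post-selection analysis
  cohort; `select_cohort()` exists for external data and is tested on
  hand-built tables.

## Problem sizes used by the test suite

The suite runs the full studies at reduced scale, chosen to keep each
check statistically meaningful: structural feature counts at n = 800;
CV bookkeeping (100 x 10 folds = 1000 AUCs per mode) at n = 500 with 3
variables, a 50-term vocabulary and a fixed penalty; the model-ordering
property at n = 5000 with R = 10 repetitions, 8 variables, a 100-term
vocabulary and a 3-point penalty grid; calibration type-I error over 500
replicates of n = 5000; and GCS trend recovery at n = 10 000. The
acceptance script (`scripts/acceptance.R`) regenerates all of these
quantities from scratch at comparable sizes.

## Known limitations

- The trajectory measure set is a reconstruction constrained by the
  8-per-variable arithmetic; other reasonable sets (e.g. time-weighted
  means) exist.
- The TF-IDF dialect (smoothed IDF, natural log, no normalization) is one
  of several defensible conventions; it is configurable in spirit but the
  package ships a single dialect.
- Pooled-mode vocabularies are fitted on the pooled corpus; per-site
  vocabularies are used only in cross-site mode.
- The inner loop tunes only the ridge penalty, not the vocabulary size.
- Bootstrap CIs on fold AUCs ignore the dependence between folds sharing
  training data; this is the convention the reported studies use, and the
  package implements it literally.
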