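---
title: "Patient-personalized recovery assessment and prognosis modelling for sudden hearing loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-personalized recovery assessment and prognosis modelling for sudden hearing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppsc)
```

## The clinical problem

Idiopathic sudden sensorineural hearing loss (ISSHL) is a loss of at least
30 dB HL over at least three contiguous audiometric frequencies arising
within 72 hours with no identifiable cause. Roughly a third to a half of
patients recover under steroid treatment, and predicting who will recover
one month after treatment matters for counselling and for escalating
therapy.

Recovery is conventionally graded with Siegel's criteria applied to the
mean pure-tone threshold over a *fixed* frequency band (0.5, 1, 2, 3 kHz),
regardless of where an individual patient's loss actually sits. A patient
with a purely low-frequency loss (say 0.125–1 kHz) can be graded "complete
recovery" on the fixed band — which was never impaired — while their
actually impaired frequencies remain 45 dB down. The patient-personalized
variant implemented here (PPSC) applies the same Siegel grading, but over
the patient's own *impaired frequency range*: the longest contiguous run of
at least three frequencies at or above 30 dB HL in the initial affected-ear
audiogram, i.e. the same run that defines ISSHL onset.

## The scoring rules

**Impaired-range detection** (`detect_impaired_range()`): on the fixed
8-frequency grid (0.125–8 kHz), find all contiguous runs of thresholds
≥ 30 dB, keep those of length ≥ 3, and select the longest (ties broken
towards the lowest frequency). Isolated impaired frequencies — the classic
example is a single impaired 8 kHz next to a low-frequency run — are
excluded, because a single frequency does not constitute the contiguous
loss that defines the disease. The tie/selection rule is a package decision
(the source material only ever shows a single-run example); it is
deterministic and reproduces that example. Missing thresholds never qualify.

**Siegel grading** (`siegel_classify()`), with `gain = initial − month1`
mean threshold over the chosen frequency set:

| class    | rule                                   | recovered |
|----------|----------------------------------------|-----------|
| complete | month-1 mean ≤ 25 dB (gain irrelevant) | yes       |
| partial  | gain > 15 dB and month-1 in (25, 45]   | yes       |
| slight   | gain > 15 dB and month-1 in (45, 75]   | no        |
| none     | otherwise                              | no        |

Two boundary decisions are worth spelling out. A gain of *exactly* 15 dB
does not grant recovery (the recovery-granting rules are strict
inequalities; the non-recovery rule's "< 15" leaves 15 itself unassigned,
and we resolve it conservatively). The band edges 45 and 75 are inclusive
upper bounds, matching the inclusive "25 dB or lower" style of the complete
rule. Severity categories are half-open bands `[lo, hi)` at 40/60/80/100 dB,
with level 5 = `[100, ∞)`.

**Exclusion cascade** (`apply_exclusion_cascade()`): five ordered rules —
duplicate record, missing month-1 affected-ear audiometry, missing
initial audiometry in either ear, bilateral disease, no qualifying run —
each patient removed at the *first* rule it violates. The order matters
for the per-rule counts but never for final membership.

**Assessment shift**: both variants grade the same patients, and the shift
between them is summarised as a 2×2 variant-by-status table with the two
reclassification counts. The primary significance test is the Pearson
chi-square on that table *without* continuity correction — this treats the
two assessments as independent samples, which is how the comparison is
conventionally reported (the uncorrected statistic on the published
marginals is 2.61, p = 0.106; the Yates-corrected one would be ≈ 2.42, so
uncorrected is clearly what was computed). A paired McNemar view,
statistically the more defensible test for same-patient assessments, is
exposed separately as `mcnemar_shift()`.

## The synthetic cohort generator

The study cohort is not publicly available, so every stage of the package
runs on a seeded synthetic stand-in (`generate_cohort()`). The generator is
first-class, tested code, and its defaults *are* the study conditions:

* **Latent prognosis.** Each patient draws a uniform latent score; the top
  37.9% form the recovered stratum (the published recovery rate under the
  personalized criteria). All covariates condition on this stratum, which
  is scaffolding for the synthetic world — the source material only
  implies marginal associations.
* **Audiograms.** The initial affected-ear audiogram is built from one of
  five shape templates (ascending, U-shaped, descending, flat, deaf) in
  5-dB steps with bounded ±5 dB jitter. Template contrasts are large
  enough that the shape classifier provably round-trips and a qualifying
  run always exists. The severity target is log-normal per stratum,
  matched to the published affected-ear medians and interquartile ranges
  (75.63 dB non-recovery vs 61.25 dB recovery), clipped to each shape's
  feasible window. Shape mix per stratum follows the published
  proportions (e.g. deaf audiograms: 30.2% of non-recovery vs 4.1% of
  recovery patients).
* **Post-treatment audiograms.** Per-frequency gains depend on the latent
  prognosis (higher prognosis → larger gain). The run-mean is steered into
  a *class-safe window* — e.g. partial recovery targets a month-1 run mean
  in [27.5, 42.5] with gain ≥ 17.5 — so that the planted grade always
  survives 5-dB quantisation. Recovery labels are therefore *emergent*:
  they are recomputed from the audiograms by the scoring code, never
  stored as independent truth, and the round trip is asserted in tests.
* **Clinical covariates.** Variables with published recovered/non-recovered
  contrasts (age, triacylglycerol, blood urea nitrogen, creatinine,
  treatment delays, hypertension, diabetes, myocardial infarction/angina,
  dizziness, tinnitus, sex) follow normal or log-normal distributions
  quantile-matched to the published medians/IQRs or Bernoulli rates per
  stratum. The remaining features use pooled clinically plausible ranges.
  BMI and the neutrophil–lymphocyte ratio are derived from their parents
  before masking.
* **Missingness** is completely at random, per feature, at the published
  rates where those exist (triacylglycerol 40.1%, onset-to-ITDI delay
  39.9%, BUN 12.1%, creatinine 9.8%, small rates for comorbidity flags)
  and at plausible chart-review rates elsewhere. Audiometric summaries and
  the outcome are never masked. Only the marginal rates are published, so
  no informative-missingness mechanism is modelled.
* **Planted violations** for the exclusion cascade are appended on demand,
  each constructed to violate exactly its own rule, so cascade counts can
  be asserted exactly (1185 planted patients → 581 survivors).

What the generator deliberately does **not** emulate: the joint dependence
structure among clinical covariates (only marginals and stratum contrasts
are calibrated), informative missingness, longitudinal audiometry beyond
the two time points, and measurement correlation between ears beyond the
affected-worse-than-unaffected ordering. Consequently, a model's absolute
performance on this synthetic world says nothing about clinical
performance; what passing tests *do* show is that every computational
stage — scoring, statistics, imputation, validation protocol, ensemble,
attribution — behaves correctly and reproduces the published worked
examples and summary statistics. The emergent run-length distribution is
close to, but not exactly, the published one (≈80% full-grid runs vs
69.4%), a consequence of driving audiogram construction from shape and
severity alone.

## Preprocessing

Imputation is round-robin chained equations (`mice_fit_transform()`):
median initialisation, then per feature — fewest missing first — a
ridge-regularised linear regression on all other features overwrites the
missing cells, cycling until the largest imputed-cell change is below
`tol = 1e-3` standard deviations or 20 cycles. Ridge (relative penalty
`1e-3`, scaled by n) is used because the 50-feature matrix contains
derived, strongly collinear columns (BMI, the one-hot treatment and shape
blocks); an unpenalised regression would be singular. Categorical and
binary features are imputed on the linear scale and only afterwards
rounded half-away-from-zero and clipped (`round_integer_features()`),
matching the pipeline order "impute, round integers, scale". Min–max
scaling maps the training range to [0, 1]; constant features map to 0, and
held-out values may fall outside [0, 1] — deliberately, since clipping
would leak no information but would distort the test distribution.

All preprocessing state is fitted on training rows only and applied frozen
to held-out rows; the tests probe this with mutation experiments
(perturbing held-out rows cannot change any imputed value).

The split machinery (`make_split_plan()`) is a stratified 80/20 train/test
split, ten independently shuffled stratified 5-fold partitions of the
training rows for validation, and 3-fold inner tuning. Stratification
deals shuffled class members round-robin, so fold class counts differ by
at most one patient. With 581 patients and 220 positives this yields a
116-patient test set with 44 positives.

## The model zoo and evaluation protocol

Eight families are tuned by exhaustive grid search maximising mean AUROC
over the inner folds (ties → earlier grid row), then refit on the full
training rows: L2 logistic regression (penalty parameterised by `C`, as
`lambda = 1/(C·n)`), a cost-complexity-pruned decision tree (grown at
`cp = 0`, then pruned at the absolute per-observation penalty `α`,
rescaled to the tree's root risk), a bootstrap forest of pruned trees with
random feature subspaces, a soft-margin linear SVM with Platt-calibrated
probabilities, discrete AdaBoost over depth-1 stumps, level-wise
gradient-boosted trees, leaf-wise (loss-guided, 31-leaf) gradient-boosted
trees, and k-nearest neighbours with uniform or inverse-distance voting.
Inverse-class-frequency weighting applies to the logistic, tree, forest,
SVM and leaf-wise-boosting families; the two remaining boosters run
unweighted. The shipped full grids are exactly the published search
spaces; because the full boosting grids are enormous (768 points for one
family), the repeated-validation and pipeline defaults use the compact
single-point grids at the published optima (`default_grids(full = FALSE)`)
— the full grids remain available and tested.

The soft-voting ensemble is the unweighted mean of the eight positive-class
probabilities; labels threshold at 0.5 with ties classified positive (no
threshold is prescribed by the source material; 0.5 with tie-to-positive
is the natural choice for a probability average).

Validation runs the full preprocessing + tuning + fitting inside each of
the (repeat × fold) cycles and reports per-model means over all cycles,
with a percentile interval of the cycle AUROCs. The test evaluation fits
everything once on the training partition and scores the untouched test
rows; its AUROC interval is a stratified bootstrap (2000 resamples by
default, percentile interval, seeded) — the interval method is a package
decision, as none is prescribed. AUROC itself is computed rank-based
(tie-corrected pairwise concordance), which equals trapezoidal integration
of the empirical ROC curve; both identities are asserted against
brute-force oracles in the tests.

## Attribution

Shapley values for the best test-phase model are estimated by permutation
sampling on the positive-class probability scale: features enter in random
order, absent features take values from a background row drawn per
permutation (default background: 100 seeded training rows). Because each
permutation's contributions telescope to `f(x) − f(z)`, the per-patient
attributions sum *exactly* to the prediction minus the patient's sampled
baseline — local accuracy holds to machine precision, and the linear-model
closed form `β_j (x_j − mean background)` is recovered within Monte-Carlo
error. A model-agnostic estimator was chosen because the ensemble is
heterogeneous; tree-specific fast paths would cover only some components.
Features are ranked by mean absolute attribution, with a direction summary
(correlation of feature value with attribution) standing in for the
beeswarm colour axis.

## Numerical and scale choices

* Thresholds are accepted at any real value in [−10, 120] dB by the
  scorers; the generator emits 5-dB steps. Averages keep full precision.
* Problem sizes in the shipped tests and acceptance script: property
  suites run at n ≤ 600; generator calibration checks at n = 5000–5810;
  the null (label-permuted) and planted-signal modelling runs use the
  full 581-patient cohort with a 2 × 5 repeated-validation protocol and
  compact grids. These sizes were chosen so the whole suite runs in a few
  minutes while keeping every Monte-Carlo band at ≥ 2.5 standard errors.
* The null run is constructed by permuting outcome labels — the cleanest
  zero-signal world, since a "no-effect" generator configuration would
  still couple outcome to severity through the feasibility constraints of
  the grading itself.
* Seeds: one master seed fans out additively to the generator, split
  plan, per-family fits, bootstrap and attribution; every artifact of
  `run_pipeline()` records it.

## Known limitations

The synthetic world is calibrated to published *marginals*; real-data
correlation structure, informative missingness and audiometric
test–retest behaviour are out of reach, so model performance figures from
this package characterise the pipeline, not the clinic. The traditional-
variant recovery rate is emergent (not separately calibrated), so the
synthetic assessment-shift table differs numerically from the published
one — the published table itself is reproduced exactly from its printed
marginals. Attribution directions for weak features are noisy at the
default permutation budget; increase `n_perm` for stable rankings beyond
the leading features.
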