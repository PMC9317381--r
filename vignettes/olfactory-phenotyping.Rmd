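---
title: "Discovering olfactory phenotype structure with olfclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering olfactory phenotype structure with olfclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical olfactory testing conventionally reduces the sense of smell to
three numbers — odor threshold, discrimination and identification — whose
sum (the TDI score, 1–48) assigns a diagnosis of anosmia (< 16.5),
hyposmia (16.5–30.5) or normosmia (> 30.5). Extended batteries add tests
such as odor-dilution sorting, odor-distance perception, trigeminal
lateralization, enantiomer discrimination, post-adaptation thresholds and
an importance-of-olfaction questionnaire, producing a small subjects ×
variables table (on the order of 135 × 15 plus age, sex and BMI). The
scientific question is whether this richer phenotype contains subgroup
structure that the three classical scores do not explain, and which
variables carry that structure.

`olfclust` implements the complete workflow: instrument scoring,
distribution-aware preprocessing, unsupervised structure detection,
nonparametric subgroup statistics, a 17-method cross-validated
feature-selection ensemble consolidated by computed ABC analysis, and
holdout validation by balanced accuracy — together with a synthetic
cohort generator so that every stage can be exercised and tested without
access to clinical data.

## The synthetic cohort generator

`generate_cohort()` draws subjects from a latent multivariate Gaussian
with unit variances and a planted two-cluster structure (default 80/55
of 135). The between-cluster mean shift of each variable equals its
configured Cohen's d, applied on the latent scale *before* marginal
transforms, so effect sizes remain interpretable. The default effect
profile concentrates the signal in the four sorting-task variables
(|d| 1.0–1.3), with importance-of-application at 0.8, the odor distances
at 0.7, the Sniffin' subtests at 0.35–0.45 and everything else at 0.2 or
below. Thresholds and distances get lognormal (right-skewed, positive)
marginals by exponentiating the latent scale; 4% of olfaction cells are
masked missing-completely-at-random (covariates stay complete, since
covariates are never imputed downstream).

Correlation structure: the three questionnaire subscales, the two
nostril distances, and the non-threshold Sniffin' subtests form
within-block correlation blocks (default r = 0.5, configurable — real
within-cluster covariances are unknown, so these are judgment calls that
the tests vary). In addition each raw sorting score is correlated at
r = 0.7 with its time-corrected counterpart: both derive mechanically
from the same sorting performance, and treating them as independent
would misrepresent the battery. Sex is Bernoulli with cluster-dependent
probability of being female (0.70 vs 0.49); age and BMI get small
cluster shifts.

What the generator does *not* emulate: integer-valued scores (variables
stay continuous on plausible scales), missing-not-at-random mechanisms,
floor/ceiling effects, and any joint structure beyond the stated moments
and blocks. Tests passing on this generator therefore demonstrate that
the pipeline recovers the structure it assumes, not that real cohorts
contain such structure.

A behavioral-level simulator is included for the sorting task itself:
`generate_sorting_responses()` draws permutations from a Mallows model
centered on the correct ordering, sampled exactly by repeated insertion.
A single dispersion parameter per cluster controls noise: dispersion 0
yields perfect sorting, and the expected footrule score grows with
dispersion. The Mallows model was chosen because it is the standard
exactly-samplable permutation noise model with one concentration
parameter; no behavioral model is prescribed by the instrument.

## Instrument scoring

- **Sorting score**: the subject's arrangement of five dilutions is
  scored as the Spearman footrule, the sum over items of the absolute
  difference between assigned and true rank. The per-item error is the
  instrument's definition; summing to a per-test scalar is the package's
  convention (it is the quantity used downstream, and exhaustive
  enumeration of all 120 permutations confirms the score is an even
  integer in [0, 12]).
- **Time correction** divides the raw score by the task duration in
  seconds (errors per second). The instrument does not fix this
  definition; errors-per-second is consistent with the magnitude of
  published group means (~0.05–0.06) and is homogeneous of degree −1 in
  duration.
- **TDI and diagnosis** per the cut-offs above; the hyposmia band is
  treated as the closed interval [16.5, 30.5] since its neighbors are
  defined by strict inequalities.
- **Odor distance**: mean of three trials per nostril, 0–30 cm.
- **Lateralization / enantiomer** scores are counts of correct trials
  (40 and 4 trials respectively).
- **Questionnaire**: three subscales of six 0–3 items (maximum 18);
  aggravation/lie items are ignored by design.

## Preprocessing

Each olfaction variable (and BMI) is examined on Tukey's ladder of
powers {−2, −1, −1/2, 0 (log), 1/2, 1, 2}; negative rungs are negated so
every rung is monotone increasing, and an offset of `1 − min(x)` is
applied to non-identity rungs when nonpositive values occur. The rung
maximizing the D'Agostino–Pearson omnibus p-value is selected, with ties
broken toward the identity and then the smaller absolute power. The
omnibus statistic K² = z²(skewness) + z²(kurtosis) is implemented from
the standard normalizing transformations and referred to χ²(2); at least
20 observations are required. One deliberate divergence from a popular
implementation: for *exactly* zero sample skewness the skewness z-score
is 0 here (some implementations substitute an arbitrary constant in that
measure-zero case).

Variables, then cases, with 20% or more missing cells are dropped
(strictly-less-than-20% retention). Remaining missing olfaction cells
are imputed by chained random forests (MICE-style: median
initialization, then five cycles of per-variable forest regression on
all other variables, 100 trees, fixed seeds). Observed cells are never
modified, and forest predictions are convex combinations of observed
values, hence in-range. Finally `z_standardize()` centers and scales
the olfaction block (sample SD, denominator n − 1 — stated for
bit-reproducibility).

## Unsupervised structure

PCA is computed on the standardized olfaction block; components with
eigenvalues > 1 are retained (Kaiser–Guttman), with a fallback to one
component plus a warning if none qualifies. Component signs are fixed so
each component's largest-magnitude loading is positive, making the
projection deterministic.

Variable importance weights each variable's association with each
retained component (the dot product of the z-scored variable with the
component scores), z-transformed *within component* — column-wise, so
variables remain comparable inside a component; the formula's
z-transform is ambiguous between column-wise and whole-matrix, and
column-wise was chosen — then scaled by the component's
explained-variance fraction. The importance is the absolute row sum over
retained components; computed ABC analysis requires positive data while
signed row sums can be negative, so the absolute value is used and the
signed version is exposed as an attribute. A consequence worth knowing:
for near-exchangeable variables the within-component z-transform
amplifies tiny association differences, so single-draw importances
scatter; symmetry holds in expectation (and is tested that way).

Clustering uses k-means (Lloyd, k-means++ initialization, 25 restarts,
tolerance-free 300-iteration cap) on the retained component scores with
Euclidean distance. The number of clusters is selected among k = 2..5 by
the mean silhouette width, ties toward the smaller k; a best silhouette
below 0.1 flags "no reliable structure" (threshold configurable).
Stability is assessed by 20 bootstrap resamples: each is re-clustered at
the reference k, and the adjusted Rand index between resample labels and
reference labels is evaluated on the unique resampled subjects (the
comparison set is not prescribed; unique-subject comparison avoids
double-counting duplicates). Degenerate single-cluster resamples score
ARI 0. Ward agglomerative clustering and partitioning around medoids are
fitted at the same k for an apples-to-apples silhouette comparison.

## Group statistics

Two-group comparisons use Mann–Whitney U (midrank ties; exact null
distribution for tie-free samples with n1·n2 ≤ 400, tie-corrected
normal approximation otherwise), Cohen's d with pooled SD (positive =
larger in the second group), and Pearson χ² for 2 × 2 contingencies.
Yates continuity correction is ON by default for observed
cross-tabulations and exposed as a flag: published values of this
statistic family mix conventions, and the package reproduces either on
request. Bonferroni correction divides α = 0.05 by the number of tests
(18 for the full battery: 15 olfaction variables, age, BMI, and the sex
contingency).

## The feature-selection ensemble

After a stratified 20% holdout is set aside, hyperparameters are tuned
per algorithm by 5-fold cross-validated grid search on balanced
accuracy. The three algorithms are a linear max-margin classifier
(libsvm), random forests, and penalized logistic regression. One
deviation from the symmetric design: libsvm supports only L2-regularized
hinge loss, so the margin classifier's grid walks the penalty strength
(10^−3..10^3) without a penalty-type axis; the ridge/LASSO choice
applies to the logistic model (glmnet, α ∈ {0, 1}), and no installed
library provides an L1-penalized linear SVM. Forest grid: {100, 200}
trees × depth {5, 10, unlimited}; ties resolve to 200 trees of depth 10.

Seventeen selection methods then run: PCA importance (olfaction
variables only — age/sex/BMI are structural zeros in that row), absolute
Cohen's d, and five schemes × three algorithms over a repeated
stratified 5-fold × 20-repeat scheme (100 runs):

- **SKB**: top-k by one-way F statistic; k tuned once per algorithm over
  1..p on the training set (the alternative — re-tuning k inside every
  run — is a plausible reading but was not adopted).
- **SFM**: importance above the mean importance of the run's model (a
  common default; no threshold is prescribed).
- **RFE**: eliminate the least important variable until half remain (no
  retained-count rule is prescribed; half is fixed and reported).
- **SFS forward/backward**: greedy add/remove maximizing balanced
  accuracy on the run's held-out fold, stopping when no step improves by
  more than 1e-4. Evaluating candidates on the run's held-out fold —
  rather than a nested cross-validation inside each run — keeps the
  ensemble a pure function of (data, seed) at tractable cost.

Each method's per-variable record (counts over runs, or absolute
importances for the two univariate methods) is consolidated by computed
ABC analysis; the final reduced set is the ABC set A of the per-variable
sum of A-memberships (0..17). Re-running the ensemble against a second
target (e.g. the clinical diagnosis) and differencing the sum scores
contrasts what drives clusters versus diagnosis.

### Computed ABC analysis

Items are sorted descending (stable on ties) and the cumulative
contribution curve is interpolated linearly from (0,0) to (1,1). The A|B
boundary is the curve point nearest to the ideal point (0,1); the B|C
boundary is the break-even point where the segment slope first drops to
≤ 1, constrained not to precede A|B. These geometric rules follow the
published computed-ABC method; exact agreement with other
implementations on boundary-adjacent items is not guaranteed, and such
divergences should be reported rather than silently resolved. Set
membership is scale- and permutation-invariant, and A is always a prefix
of the descending order.

## Holdout validation

Per run (default 100), a stratified random 80% of the training subjects
fits each classifier on each feature set (full / reduced / sparse
two-variable), and a stratified random 80% of the validation subjects is
scored. Cells report the median balanced accuracy with a nonparametric
95% CI (2.5th–97.5th percentiles). Stratified subsampling (not
prescribed) avoids empty-class fits at these sample sizes; a cell whose
validation subsample lacked a class in more than half of the runs is
flagged unstable.

## Problem sizes and numerical choices

The package's own test and demonstration sizes: cohorts of n = 135
(80/55); 20-seed replication for structure and selection recovery; the
selection-recovery replication runs the ensemble with a 5-fold × 1-repeat
scheme (5 runs per method) — recovery of the planted sorting variables
is already stable at that depth, and the full 5 × 20 scheme is used for
single-cohort reports such as the acceptance script. Randomness is
always derived from a single master seed (per-stage offsets), so every
report is bit-reproducible. k-means uses 25 restarts and 300 Lloyd
iterations; imputation uses 5 cycles of 100 trees; ABC uses exact
geometry with a 1e-12 slope tolerance.

Known limitations: recovery statements are relative to the generator's
assumptions; the bootstrap-stability ARI of the default synthetic
profile is moderate (≈0.6–0.9 across seeds, as expected at a total
planted Mahalanobis separation of ≈2.6σ spread over 5–7 retained
components), so stability readouts should be interpreted as a property
of the data at hand, not a fixed pass/fail bar; and the clinical meaning
of any detected cluster is out of scope.

## A minimal run

```{r, eval = FALSE}
library(olfclust)

cfg <- run_config(seed = 1, scheme = cv_scheme(5, 20, seed = 401),
                  output_dir = "olfclust-report")
report <- run_pipeline(cfg)

report$clustering$best_k
report$clustering$stability$mean_ari
report$selection$final_set
report$validation
```
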