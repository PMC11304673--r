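---
title: "Modelling cardiometabolic-continuum trajectory patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiometabolic-continuum trajectory patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmctraj)
```

## The model

The cardiometabolic continuum (CMC) views hypertension (HYP), diabetes
mellitus (DM), heart disease (HD: angina, myocardial infarction or heart
failure) and stroke (STK) not as isolated endpoints but as a chained
temporal sequence within one individual. `cmctraj` represents a
participant's continuum by the 4-tuple

$$(t_{HYP},\; t_{DM},\; t_{HD},\; t_{STK}), \qquad 0 < t_i \le 1,$$

where $t_i$ is the disease's onset time divided by the participant's
follow-up duration and $t_i = 1$ encodes absence during follow-up. A
participant with hypertension after 2 years and diabetes after 4 years of a
10-year follow-up is the point $(0.2, 0.4, 1, 1)$. The encoding keeps the
temporal ordering of the chain, puts all four coordinates on a common
scale, and gives disease-free participants a single well-defined location
(the corner $(1,1,1,1)$) rather than missing values.

Two conventions the encoding forces are worth stating. Ties at identical
occurrence fractions are ordered by the canonical disease order HYP < DM <
HD < STK, and a tie flag is carried so reports can mark the ambiguity; the
data carry no within-time ordering, so any other convention would be
equally arbitrary. An event at exactly the end of follow-up encodes to
$t_i = 1$ but keeps its occurrence flag, so cluster profiling does not
confuse it with absence; clustering itself uses the times only.

Pattern discovery runs k-means (Lloyd's algorithm) on the raw tuples. No
feature scaling is applied: all four coordinates already live on $(0,1]$.
The number of clusters is chosen by the average silhouette over a candidate
range (default 2–8), and discovered clusters are named by explicit rules
evaluated in precedence order:

1. **Healthy** — at least 88% of members disease-free;
2. **FirstHD** — everyone developed heart disease and it came first for at
   least 75% of members;
3. **FirstDM** — everyone developed diabetes and it came first for at
   least 78%;
4. **EarlyHyp** — everyone developed hypertension, it came first for at
   least 92%, and at least 95% of hypertension onsets lie within the first
   40% of follow-up;
5. **LateHyp** — as EarlyHyp but with onsets in the 40–80% window.

A cluster matching no rule is `Unlabeled`. The thresholds are the weakest
of the published per-stratum bounds (the rules were reported with
stratum-specific strictness, e.g. 75% vs 90% for the HD-first rule), so a
single configuration labels every stratum; all of them are exposed in
`label_rules()`.

Pattern membership is then predicted from baseline covariates with a
multiclass probability random forest evaluated under repeated stratified
outer cross-validation (default 10 folds, 5 repeats) with 5-fold inner
tuning, and explained with path-dependent TreeSHAP attributions computed on
held-out rows only.

## Why the evaluation design is this strict

The pattern classes are severely imbalanced (the Healthy cluster holds
66–92% of a stratum, the smallest clusters under 2%), so a naive
evaluation over-rewards majority prediction and a naive oversampling
scheme leaks information. `run_nested_cv()` therefore:

* refits imputation (median/mode), standardisation and one-hot encoding
  inside every training partition, including every inner-CV training part —
  test rows never influence a transformer;
* applies SMOTE (convex combinations of same-class nearest neighbours)
  strictly after preprocessing and strictly to training partitions;
* reports support-weighted precision, recall and F1 plus plain accuracy as
  mean (SD) over all outer folds. Plain accuracy coincides with weighted
  recall, which is why both are printed: the pairing makes the redundancy
  visible instead of hiding an ambiguous "weighted accuracy".

A deliberately broken variant (`smote_timing = "pre_split"`) oversamples
before splitting; on imbalanced noise it scores systematically higher than
the correct pipeline, which the test suite asserts as a directional
leakage check. The variant exists only for that demonstration.

Fold assignment and every seeded draw downstream (SMOTE, forest fits) are
made over a content-canonical row order, so results are invariant to how
the input table happens to be sorted — a property the tests verify
exactly.

## SHAP choices

Attributions use the path-dependent TreeSHAP recursion (implemented in
compiled code over the fitted ranger trees) in predicted-probability
space, one attribution vector per held-out row and class. The
path-dependent variant needs no background data set: node weights come
from the training rows of each fold's own model, which keeps the
computation deterministic and fold-contained. Additivity — base value plus
attribution sum equals the predicted class probability — holds to
floating-point accuracy and is asserted at $10^{-6}$.

One-hot levels are reported individually (`education.Sec` style), because
the directionality of a level is the quantity of interest; a sum-over-
levels aggregation would cancel opposing level effects. Pooling across
repeats is plain concatenation (each participant appears once per repeat);
`pool = "per_repeat_average"` provides the averaged alternative.

## The synthetic cohort generator

No public individual-level data exist for the two source cohorts, so the
package ships a generator that emulates their published structure and
makes every stage testable:

* five latent patterns with the published per-stratum mixing proportions
  (e.g. Healthy = 8490/9242 for UK-dialect women) and time windows
  (EarlyHyp hypertension within 40% of follow-up, LateHyp within 40–80%,
  stratum-specific windows for the DM- and HD-first patterns);
* first-disease times uniform within the pattern window; secondary
  diseases per-disease Bernoulli, placed uniformly on the remainder of
  follow-up (`secondary_gap_max` shortens that interval if a tighter
  coupling is wanted);
* covariate-dependent membership through a softmax over
  `log(mixing proportion) + covariate effects`, with two covariate
  dialects (UK-style and Brazilian-style schemas) plus a shared
  anthropometric/clinical block — means, SDs and default effects are
  documented conventions, not published values;
* MCAR covariate missingness at a configurable rate (the source analyses
  describe imputation but not a missingness mechanism, so anything beyond
  MCAR would be invention);
* one master seed; every stage derives its own substream through a fixed
  affine map (`derive_seed`), so stages re-run independently and runs are
  byte-reproducible.

What the generator does **not** emulate: informative censoring, competing
mortality, visit-based ascertainment granularity, within-pattern members
whose first disease differs from the pattern's designated one, and
realistic covariate correlation structure. Passing tests on this synthetic
therefore show that the pipeline recovers structure it is pointed at, not
that the published epidemiology is reproduced.

## Numerical and design notes

* **k-means**: Lloyd iterations with best-of-`n_init` seeded restarts by
  inertia; an emptied centroid is reinitialised at the point farthest from
  its assigned centroid, deterministically. The in-package implementation
  exists because this restart-and-repair contract (and hence bitwise
  determinism) is part of the method; it is cross-checked against
  `stats::kmeans` on separable fixtures.
* **Silhouette**: computed with the `cluster` package over all points up
  to 20,000, and over a seeded uniform subsample beyond (the distance
  matrix is quadratic in n). A best mean silhouette under 0.25 raises a
  low-separation warning.
* **k selection on the emulation**: the silhouette curve of the emulated
  strata is nearly flat from five clusters upward (differences under
  0.005). The published cluster tables themselves show why: the DM-first
  and HD-first patterns each contain a "second disease followed" subgroup
  and a "no second disease" subgroup, and the encoding places the latter
  at a point mass ($t=1$), so a well-optimised k-means at k > 5 can always
  peel these apart for a sliver of silhouette. With five clusters the
  planted structure is recovered essentially exactly (adjusted Rand index
  above 0.99 at the documented sizes) and all five rule-based labels are
  assigned exactly once; the argmax of the silhouette, however, may land
  above five on this synthetic. `cmc_patterns(k = 5)` pins the cluster
  count when the analysis calls for it.
* **Hyperparameter grid**: trees in {200, 500}, depth in {unbounded, 10},
  minimum node size in {1, 5}, selected by inner-CV weighted F1. The
  evaluation design fixes the CV structure but not the grid, so the grid
  is a package convention, deliberately small.
* **Tiny classes**: a class smaller than the outer fold count is pooled
  into one stratum for splitting (true labels kept for scoring) with a
  warning; SMOTE skips singleton classes with a warning and uses
  `min(k, class size − 1)` neighbours otherwise.
* **Statistical tests**: Pearson chi-square without continuity correction,
  one-way ANOVA (`oneway.test`, equal variances), Kruskal-Wallis with tie
  correction; significance at p < .05; no multiple-testing adjustment, and
  reports say so.
* **Display rounding** is half-away-from-zero at the precision of the
  corresponding published tables; machine output keeps raw values.

## Problem sizes used by the test suite

The suite regenerates everything in code: cluster-recovery checks run one
emulated stratum at n = 5,000; classifier sanity checks use n = 2,000
(separable and permuted) and n = 600 (leakage direction) under a reduced
CV profile (5 outer folds, one repeat, single-point grid, 100 trees);
SHAP driver-recovery uses 20 replicates at n = 300; the type-I error study
uses 2,000 null replicates per test; pipeline determinism runs the bundled
quick profile twice at n = 200. These sizes were chosen so the whole suite
exercises every contract at desk scale while the full-size emulation
remains available through `profile = "emulation"`.

## Limitations

Rule thresholds, generator covariate effects and the hyperparameter grid
are conventions that a user studying a real cohort should revisit.
Attribution rankings are conditional on the random forest; a different
classifier family can reorder them. Sign-concordance summarises
directionality crudely for continuous features with non-monotone effects.
And the synthetic cohorts, by construction, cannot validate
epidemiological conclusions — only the mechanics of the method.
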