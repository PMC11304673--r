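# cmctraj

Multimorbidity trajectories along the cardiometabolic continuum (CMC): the
temporal chain of hypertension (HYP), diabetes (DM), heart disease (HD)
and stroke (STK) onsets within one individual. `cmctraj` is for
biostatisticians and epidemiologists who want to discover temporal
patterns in multi-disease cohorts and ask which baseline characteristics
predict them, with an evaluation design that survives severe class
imbalance.

## The method

Each participant's continuum is encoded as a 4-tuple of fractional
occurrence times

```
(t_HYP, t_DM, t_HD, t_STK),   0 < t_i <= 1,
```

where `t_i` is onset time divided by follow-up duration and `t_i = 1`
means the disease did not occur. Hypertension after 2 years and diabetes
after 4 years of a 10-year follow-up is the point `(0.2, 0.4, 1, 1)`.
The pipeline then:

1. clusters the raw tuples with k-means (seeded multi-restart Lloyd), the
   cluster count chosen by average silhouette;
2. names clusters by explicit rules — **EarlyHyp** (hypertension first,
   within 40% of follow-up), **LateHyp** (40–80%), **FirstDM**,
   **FirstHD**, **Healthy** — with configurable thresholds;
3. summarises incidence, onset timing and ordered trajectory patterns
   (`DM->HYP` style), with chi-square / ANOVA / Kruskal-Wallis group
   comparisons;
4. predicts pattern membership from baseline covariates with a multiclass
   random forest under repeated stratified nested cross-validation —
   imputation, standardisation, one-hot encoding and SMOTE oversampling
   all refitted inside each training partition, never on test rows;
5. explains the classifier with path-dependent TreeSHAP attributions
   computed on held-out folds only, in predicted-probability space
   (additive to the prediction within 1e-6), aggregated into per-class
   global importance rankings and local directionality summaries.

Because the source cohorts are access-restricted, the package ships a
seeded synthetic-cohort generator (`study_emulation_config()` /
`generate_cohort()`) that reproduces their published stratum structure:
five latent patterns at the published mixing proportions, pattern-specific
onset windows, covariate-dependent membership in two cohort dialects, and
MCAR missingness. Every stage of the pipeline is tested against it.

## Worked example

```r
library(cmctraj)

tr <- encode_trajectory(data.frame(disease = c("HYP", "DM"), time = c(2, 4)),
                        follow_up = 10)
print(tr)
#> CMC trajectory
#>   4-tuple: ( 0.2, 0.4, 1, 1 )
#>   occurred: HYP DM
#>   follow-up: 10 years

cfg    <- study_emulation_config("uk", "female", n = 2000, seed = 42)
cohort <- generate_cohort(cfg)
fit    <- cmc_patterns(cohort$trajectories, k = 5, seed = 1)
print(fit)
#> CMC pattern model: 5 clusters over 2000 trajectories
#>   patterns: EarlyHyp (72), FirstDM (33), FirstHD (23), Healthy (1783), LateHyp (89)
adjusted_rand_index(fit$model$assignments, cohort$labels)
#> 0.991

covs <- cohort$covariates[, setdiff(names(cohort$covariates),
                                    c("participant_id", "sex", "follow_up_years"))]
cv <- run_nested_cv(covs, fit$labels,
                    cv_config(outer_folds = 5, repeats = 1, inner_folds = 3,
                              seed = 1,
                              grid = data.frame(num_trees = 200,
                                                max_depth = 0, min_node = 5)),
                    keep_models = TRUE)
print(cv)
#> Nested CV random forest: 1 x 5-fold outer, 3-fold inner (fold_internal)
#>   accuracy  0.890 (sd 0.005)
#>   precision 0.795 (sd 0.007)
#>   recall    0.890 (sd 0.005)
#>   f1        0.839 (sd 0.006)

shap <- compute_shap_cv(cv)
head(global_importance(shap, "EarlyHyp"), 5)
#>         feature mean_abs_shap rank  top
#> sbp         sbp    0.02538834    1 TRUE
#> dbp         dbp    0.02140828    2 TRUE
#> age         age    0.01953297    3 TRUE
#> bmi         bmi    0.01548667    4 TRUE
#> glucose glucose    0.01364691    5 TRUE
```

Reading the output: k-means at k = 5 recovers the planted five-pattern
structure almost exactly (adjusted Rand index 0.991 against the generator's
true labels). The classifier's plain accuracy (0.89) sits near the Healthy
share of the stratum — the imbalance the weighted metrics are there to
expose — and the SHAP ranking surfaces the covariates the generator
actually wired to the EarlyHyp pattern (blood pressure, age, BMI). The
SHAP step takes a couple of minutes at this size; bound `max_depth` or
reduce `num_trees` for quicker exploration.

An end-to-end stratified run (generation → clustering → labeling → tables
→ nested CV → SHAP → CSV/JSON export, with a run manifest) is

```r
run_pipeline(pipeline_config(strata = list(list(cohort_dialect = "uk",
                                                sex = "female", n = 1000)),
                             seed = 1, profile = "quick"),
             out_dir = "out")
```

or, from a shell, `Rscript inst/scripts/cmc-pipeline.R --config cfg.yaml
--out out`.

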