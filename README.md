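# omnisub

Survival-guided multi-omics subtyping of tumor cohorts.

`omnisub` implements a complete pipeline for discovering clinically
meaningful molecular subtypes in multi-platform cancer cohorts (mRNA
expression, DNA methylation, RPPA protein, miRNA), of the kind assembled
for serous ovarian cancer from TCGA-style data. The pipeline is *guided by
overall survival* at both of its decision points:

1. **Feature screening.** Every molecular feature is fit in a univariate
   Cox proportional-hazards model against overall survival; features with
   Wald *p* < 0.05 form the working feature set.
2. **Cluster sweep.** Three unsupervised algorithms — partitioning around
   medoids (PAM), hierarchical clustering (HC), and non-negative matrix
   factorization (NMF, multiplicative updates with restarts) — are each run
   for k = 2…9 clusters.
3. **Model selection.** Every candidate partition is scored by the
   k-sample log-rank test and ranked by a complexity-penalized score

       score = −log10(p) − λ·(N − 2),    λ = 1 by default,

   so extra clusters must buy real survival separation. The argmax is the
   platform's subtyping model; ties break toward smaller N.
4. **Characterization & integration.** Subtype-specific gene sets by the
   2-fold / 0.5-fold one-vs-rest rule, heatmap row ordering, hypergeometric
   enrichment against GMT gene sets, clinical-variable association (one-way
   ANOVA / chi-square), and cross-platform subtype overlap tests
   (chi-square on shared samples, per-pair stars at 0.05/0.01/0.001).

An expression matrix can additionally be converted to per-sample **pathway
activity**: gene-level log fold changes against the cohort mean are
propagated along signed, weighted pathway topologies and summed into the
net accumulated perturbation (tA) per pathway per sample; the resulting
pathway × sample matrix is then subtyped like any measured platform.

Because the real cohorts are not redistributable, the package ships a
**synthetic multi-omics generator** (`simulate_cohort`) with planted
subtypes, planted prognostic features, per-subtype exponential survival,
calibrated right-censoring and partial platform coverage, so the entire
pipeline is testable end-to-end with known ground truth. See the methods
vignette (`vignettes/methods.Rmd`) for the models, defaults and their
rationale.

## Worked example

```r
library(omnisub)

cfg <- simulation_config(n_patients = 300, k_true = 3,
                         platform_dims = c(mrna = 400, protein = 80),
                         frac_informative = 0.15, effect_size = 2,
                         hazard_per_subtype = c(0.008, 0.002, 0.0005),
                         platform_coverage = c(mrna = 1, protein = 0.8),
                         seed = 42)
cohort <- simulate_cohort(cfg)

result <- run_platform(cohort$matrices$mrna, cohort$survival, seed = 42)
print(result)
#> Platform 'mrna': 300 samples, 54/400 features selected
#> Selected model: NMF with 3 clusters (score 37.981, log-rank p 1.04e-39)
#>   cluster   n median_days
#> 1       1 100         432
#> 2       2 100        1227
#> 3       3 100         102

head(result$model$table[, c("method", "k", "logrank_p", "score", "selected")])
#>   method k    logrank_p    score selected
#> 1    NMF 3 1.044222e-39 37.98121     TRUE
#> 2    PAM 3 6.811513e-39 37.16676    FALSE
#> 3     HC 4 2.070857e-39 36.68385    FALSE
#> 4    PAM 4 5.116493e-38 35.29103    FALSE
#> 5    NMF 4 5.215765e-38 35.28268    FALSE
#> 6     HC 5 1.254113e-38 34.90166    FALSE

adjusted_rand_index(result$partition$labels,
                    cohort$true_labels[names(result$partition$labels)])
#> [1] 1
```

Reading the output: 54 of 400 mRNA features were individually prognostic
and survived the Cox screen; among 24 candidate models the NMF partition
with 3 clusters maximized the penalized score (its log-rank p of 1e-39
beats the 2-cluster candidates by far more than the one-unit penalty); the
three subtypes have sharply different median survivals (102 / 432 / 1227
days); and the recovered partition matches the planted subtypes exactly
(adjusted Rand index 1). `run_cohort()` runs every platform of a cohort and
then tests each platform's partition against the mRNA reference partition
on their shared samples (`run_integration`).

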