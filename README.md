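# mbstrat

Methylation-based subgroup discovery and risk stratification for childhood
medulloblastoma.

Medulloblastoma, the most common malignant childhood brain tumour, splits
into molecular subgroups with very different outcomes. Given a probes ×
samples matrix of DNA-methylation beta values and a clinical annotation
table, `mbstrat` provides the full analysis path used to define
seven methylation subgroups and four clinical risk tiers:

1. **Class discovery** — non-negative matrix factorisation
   `V ≈ W H` (`W`: probes × k "metagenes", `H`: k × samples scores) by
   multiplicative updates, k-means on standardised scores, and bootstrapped
   consensus clustering (default 250 iterations). Cluster-number selection
   by the cophenetic index over the full 3–10 × 3–10 metagene/cluster grid;
   samples with resampling confidence < 80% are non-classifiable (NC).
2. **Validation by projection** — non-negative least-squares projection of
   the frozen discovery basis onto an independent cohort, nearest-centroid
   classification in the frozen discovery coordinate system, and
   concordance after optimal label matching.
3. **Characterisation** — χ² enrichment panels with Pearson residuals,
   Fisher exact tests, age ANOVA, and per-group log-normal age fits whose
   weighted-density intersection defines the infant/childhood SHH age
   cutoff (4.3 years): `w₁ f₁(x) = w₂ f₂(x)`, a quadratic in `log x`.
4. **Survival modelling** — Kaplan-Meier, log-rank, 0–5-year interval
   hazard ratios, Cox proportional-hazards fits with Schoenfeld
   diagnostics, IPCW time-dependent ROC AUC at 5 years, and greedy forward
   covariate selection scored by 100 × 10-fold cross-validated AUC.
5. **Risk stratification** — rule engines for the subgroup-dependent
   four-tier scheme (favourable / standard / high / very high, anchored at
   5-year progression-free survival of 91/81/42/28%), its M+
   redistribution variant, and published comparators (PNET5-style,
   cytogenetic, group-4-only), compared by time-dependent AUC.

A synthetic-cohort generator (`sim_config()`, `simulate_cohort()`)
reproduces the statistical structure these methods assume — metagene block
structure, subgroup-specific covariate frequencies, log-normal ages
crossing at 4.3 years, tier-anchored exponential survival — so the entire
pipeline is testable end to end without patient data.

## Worked example

```r
library(mbstrat)
cfg  <- sim_config(n_samples = 150, n_probes = 600)
pair <- simulate_cohort_pair(cfg, seed = 1)

# discovery: consensus clustering at 6 metagenes / 7 clusters
run <- bootstrap_consensus(pair$discovery$matrix, k_metagenes = 6,
                           k_clusters = 7, n_iter = 100, seed = 2)
run
#> consensus_run: 150 samples, 6 metagenes / 7 clusters, 100 iterations
#>   cophenetic 0.9999, mean confidence 0.993

labels <- assign_with_confidence(run, threshold = 0.80)
concordance(labels, pair$discovery$truth$subgroup7)
#> [1] 100

# validation: project the frozen discovery metagenes onto the second cohort
harm       <- harmonise_probes(pair$discovery$matrix, pair$validation$matrix)
proj       <- project_metagenes(run$reference$nmf$W, harm$b)
val_labels <- classify_projected(proj, run$reference$kmeans)
concordance(val_labels, pair$validation$truth$subgroup7)
#> [1] 100

# four-tier risk stratification and scheme comparison
clin <- pair$discovery$clinical
table(stratify_overall(clin, variant = "base"))
#>     excluded   favourable         high     standard unassignable    very_high
#>           26           31           41           41            1           10
compare_schemes(clin, c("overall", "pnet5", "grp34"), t = 5)
#>    scheme  n       auc
#> 1 overall 98 0.7356282
#> 2   pnet5 98 0.5520405
#> 3   grp34 98 0.7356282
```

The cophenetic index near 1 says the 7-cluster solution is stable under
resampling; concordance of 100 means the clustering (and its projection
onto the independent cohort) matches the generating subgroups exactly after
label matching. In the scheme comparison the ordinal four-tier risk score
discriminates 5-year progression events far better (AUC 0.74) than the
two-tier PNET5-style comparator (0.55); `overall` and `grp34` agree exactly
here because the shared gradable samples are all group 3/4, where the
overall scheme reduces to the combined group-3/4 rules. The excluded tier
collects infants and non-irradiated patients outside the survival-modelling
window.

A command-line interface wrapping the same functions is installed at
`exec/mbstrat` with subcommands `simulate`, `cluster`, `project`,
`characterise`, `survival` and `stratify`; every run writes a parameter
manifest and log.

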