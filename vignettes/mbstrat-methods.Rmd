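---
title: "Methods: methylation subgroup discovery and risk stratification"
author: "mbstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation subgroup discovery and risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbstrat)
```

## The analysis

Childhood medulloblastoma comprises molecular subgroups with sharply
different outcomes. This package implements a complete pipeline that (i)
discovers methylation subgroups from a probes-by-samples matrix of beta
values by bootstrapped NMF consensus clustering, (ii) validates them by
projecting the discovered metagenes onto an independent cohort, (iii)
characterises them clinically (enrichment tests, age modelling), (iv)
evaluates prognostic covariates with cross-validated survival models, and
(v) assigns patients to four clinical risk tiers through explicit rule
engines. A synthetic-cohort generator with the same statistical structure
makes every stage testable without patient data.

## Class discovery

The substrate is a beta-value matrix $V \in [0,1]^{p \times n}$ (probes
$\times$ samples). Beta values are used directly, without an M-value
transform: NMF requires non-negative input, and beta values are already on
a bounded non-negative scale. Probes with any missing value are dropped
(complete-probe analysis), then the `n` most variable probes by
across-sample standard deviation are kept (`select_variable_probes()`,
default 10,000; ties at the cutoff go to the lexicographically smaller
probe ID so the selection is reproducible).

`nmf_factorise()` minimises $\|V - WH\|_F$ over non-negative $W$ ($p
\times k$ metagene basis) and $H$ ($k \times n$ scores) by multiplicative
updates. The objective is non-increasing by construction and is tracked
each iteration; convergence is declared when its relative change falls
below `tol` (default `1e-6`, `max_iter` 1000). The best of `n_restarts`
(default 10) random initialisations is kept, with $W$ columns scaled to
unit L2 norm (scale absorbed into $H$) so scores are comparable across
metagenes. Samples are then clustered by k-means on per-metagene z-scores
(`kmeans_metagene_cluster()`); standardisation stops high-magnitude
metagenes from dominating the Euclidean metric, and the frozen
standardisation parameters travel with the fit so independent cohorts can
be classified in the same coordinate system.

`bootstrap_consensus()` assesses stability: 250 iterations (the
conventional count for this procedure) resample samples with replacement,
refit NMF + k-means, and map the iteration clusters onto a full-data
reference clustering by maximum-weight bipartite matching of the overlap
table. The consensus matrix holds pairwise co-clustering frequencies among
co-appearances; a sample's confidence is the fraction of iterations
containing it in which it mapped to its modal reference cluster, and
samples below 80% confidence are non-classifiable (NC). Cluster-number
selection uses the cophenetic index — the correlation between consensus
dissimilarities and the cophenetic distances of their average-linkage
dendrogram — over the full 3–10 $\times$ 3–10 metagene/cluster grid
(`grid_search()`; ties broken by mean confidence, then the smaller cluster
count). The cluster count may exceed the metagene count: a seven-cluster
solution over six metagenes is legal and is in fact the configuration of
interest.

Design choices where the procedure was genuinely open:

* *Resampling*: sampling with replacement ("bootstrap") is the default; a
  subsampling variant (`method = "subsample"`) is available for
  sensitivity analysis.
* *Anchoring*: iteration clusters are matched to a full-data reference
  clustering at the same (metagene, cluster) pair. Confidence is computed
  from iteration-level assignments, not from the consensus matrix.
* *Per-iteration fits*: one NMF restart per bootstrap iteration (the
  consensus aggregates over 250 refits, so per-fit restarts add little),
  but 30 k-means restarts — k-means local optima are cheap to avoid and
  directly depress assignment confidence when missed.

## Cross-cohort projection

`harmonise_probes()` intersects probe sets (error below 90% retention —
heavy loss signals incompatible platforms). `project_metagenes()` solves a
non-negative least-squares problem per validation sample against the
frozen discovery basis $W$; the per-sample relative residual
$\|v - Wh\|/\|v\|$ is reported (never worse than the zero solution, by
construction). `classify_projected()` standardises the projected scores
with the *discovery* means/SDs — nothing is re-estimated from the
validation cohort, preventing leakage — and assigns the nearest discovery
k-means centroid (ties to the lower index, flagged). An unconstrained
least-squares-then-clip solver (`method = "pinv_clip"`) is kept as a
comparison mode. Consensus reclustering of a combined cohort is available
by running the clustering on the column-bound matrix; `concordance()`
scores agreement after optimal label matching, excluding NC samples by
default.

## Age modelling

The two SHH subgroups are age-separated. `fit_age_lognormals()` fits
per-group log-normal distributions by maximum likelihood (ML denominator
for sigma) and weighs them by group proportions (mixture view) by default;
an equal-weight mode exists because the weighting convention behind such
density plots is rarely stated. `intersect_lognormals()` solves
$w_1 f_1(x) = w_2 f_2(x)$: in $y=\log x$ the $1/x$ Jacobians cancel, so
the crossing is a quadratic in $y$ (linear for equal sigmas, reducing to
the geometric mean of the medians for equal weights), and the root between
the two group medians is the cutoff. `classify_shh_by_age()` assigns ages
below the cutoff (default 4.3 years) to the infant subgroup and ages at or
above it to the childhood subgroup — the boundary itself is childhood.

## Survival machinery

Survival analysis follows the usual conventions of this literature:
administrative right-censoring at 10 years (`censor_at()`); Kaplan-Meier
with Greenwood variance and log-log CIs; log-rank tests; 0–5-year interval
hazard ratios from a univariate Cox fit with Wald CIs. Cox models
(`cox_fit()`) use Efron ties by default (lower bias; Breslow available),
complete cases only, and convert the monotone-likelihood warning into an
explicit error. Proportionality is checked with scaled Schoenfeld
residuals against untransformed time (`schoenfeld_ph_test()`).

`time_dependent_auc()` implements the cumulative-case / dynamic-control
AUC at horizon $t$ with inverse-probability-of-censoring weights from the
Kaplan-Meier estimate of the censoring distribution (cases weighted by
$1/\hat G(T^-)$, controls by $1/\hat G(t)$; weights truncated away from
zero). Ties count one half, making the estimate invariant to strictly
monotone marker transforms.

`cv_forward_select()` reproduces the covariate-selection procedure:
greedy forward selection where each candidate model is scored by the mean
time-dependent AUC of its left-out-fold linear predictor over `rounds`
(default 100) rounds of `folds`-fold (default 10) cross-validation, folds
stratified by event status so each fold contains events. A candidate is
accepted if it improves the mean AUC by more than `min_gain` (default
0.005; set 0 for "any strict increase" — the source procedure says only
that variables "conferring an increase" were added). Selection is pure
greedy; no fixed entry order is imposed. Multi-level covariates should be
supplied as binary indicators, matching how such models are usually
tabulated.

## Risk stratification

Each scheme is a frozen rule engine over the clinical record, applying its
published conditions in printed order; unknown values never default
silently — a record missing a rule-relevant feature is `excluded`, and
MYC-amplified group 4 is `unassignable` in the combined group-3/4 scheme.
The overall four-tier scheme covers patients aged 3–16 years treated with
craniospinal irradiation; infant SHH is excluded outright (infants are
treated on heterogeneous radiotherapy-sparing protocols, and the source
scheme never graded them). Its M+ redistribution variant moves
non-MYC-amplified low-risk group-3/4 patients to favourable (M−) or high
(M+), which also grades low-risk patients lacking chromosome-13 data.
`compare_schemes()` encodes tiers ordinally (favourable = 1 ... very high
= 4; any monotone encoding gives the same AUC) and compares schemes on the
shared gradable samples by default.

## The synthetic-cohort generator

`sim_config()` defaults define the study conditions emulated throughout
the tests:

* **Subgroup proportions** — the discovery composition over 409 classified
  patients (WNT 33, SHH-Infant 65, SHH-Child 38, Grp3-LR 50, Grp3-HR 65,
  Grp4-LR 73, Grp4-HR 85).
* **Beta structure** — six signature blocks (5% of probes each) with Beta
  beta-values at mean 0.8 in carrier subgroups, 0.2 otherwise,
  0.5 background, concentration 30 (moderate array noise). Block
  membership mirrors the metagene portrait: one block shared by the two
  low-risk group-3/4 subgroups (hypermethylated in low-risk disease), one
  specific to childhood SHH, plus WNT, pan-SHH, group-3 and group-4 blocks
  — seven distinct binary patterns over six blocks.
* **Ages** — per-subgroup log-normals, truncated to (0.05, 18] years.
  Infant SHH is centred at a median of 1.5 y (sdlog 0.5); the childhood-SHH
  location (meanlog 2.165, median 8.7 y, sdlog 0.35) is solved in closed
  form so the proportion-weighted densities cross at exactly 4.3 years.
  Group 3 is younger than group 4; WNT is centred at 9 y.
* **Covariate frequencies** — per-subgroup portraits (CTNNB1/chr6-loss in
  WNT, desmoplastic pathology in infant SHH, TP53/TERT/MYCN/9q-loss in
  childhood SHH, MYC/LCA in high-risk group 3, i17q at 0.76 in high-risk
  group 4, 11-loss/17-gain in low-risk group 4), drawn independently
  within subgroup. Pairwise covariate correlations beyond subgroup
  structure are *not* modelled.
* **Survival** — the true risk tier is obtained by running the overall
  stratification rules on the generated covariates; progression-free
  survival is exponential with rate $-\log(S_5)/5$ anchored at
  $S_5$ = 0.91 / 0.81 / 0.42 / 0.28 per tier (0.65 for ungraded patients),
  with exponential random censoring (0.02/year) plus the 10-year
  administrative cut. Overall survival adds an exponential lag (mean 1 y)
  to event times and is used only for smoke checks.

What passing tests therefore show — and do not show: the generator
produces clean block structure, independent flags, exponential hazards and
no batch effects, probe annotation, or late-event behaviour (the real
high-risk group-4 pattern of late deaths is deliberately not modelled).
Recovery results on it demonstrate that the machinery is correct and
internally consistent at realistic sizes, not that real 450K cohorts
would separate this cleanly.

## Numerical choices and degenerate inputs

Multiplicative updates are guarded with machine epsilon in denominators;
the residual is computed from factor Gram matrices, avoiding a $p \times
n$ product per iteration. Consensus pairs that never co-appear get
consensus 0 with a warning; a bootstrap iteration whose score matrix has
fewer distinct points than clusters is skipped. The cophenetic index is an
error on zero-variance dissimilarities (uniform consensus) rather than a
silent `NA`. Degenerate age fits (identical ages, non-positive ages) and
empty risk-scheme intersections are errors. All stochastic entry points
take an explicit `seed` and are bitwise reproducible given it.

Problem sizes used by the packaged end-to-end checks (chosen as desk-scale
versions of the study design): subgroup recovery at n = 300 samples x
2,000 probes with 250 bootstrap iterations; model selection over the 3–8
grid on four-subgroup cohorts of n = 80 at 15 iterations per cell across
10 seeds (with few iterations, a bootstrap that misses some sample in every
resample becomes a real possibility, and the consensus run treats that as
an error — 15 iterations per cell makes it vanishingly rare); projection on
an independent n = 250 cohort; age-cutoff recovery at n = 5,000; forward
selection at n = 500 with 10x10-fold CV across 20 seeds; tier survival
anchors on a cohort large enough that every tier's Kaplan-Meier estimate
has a Monte-Carlo error of about one percentage point or less.

## Limitations

Infant risk modelling, treatment effects, competing risks, batch
correction, raw IDAT processing and differential-methylation analysis are
out of scope. Cohort-derived hazard ratios and survival percentages from
the motivating study are not reproducible without its patient-level data;
the package instead verifies every statistical component against
closed-form, brute-force or simulation oracles and the pipeline against
its own generative model.
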