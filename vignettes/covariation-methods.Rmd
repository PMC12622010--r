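---
title: "Methods: cell type-resolved gene-metabolite covariation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell type-resolved gene-metabolite covariation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `covomics`, the
defaults and why they are what they are, the design decisions that were
genuinely open, and what the synthetic-data tests do and do not establish
about real cohorts.

## The model

The unit of analysis is an `omics_cohort`: per-cell-type pseudo-bulk
expression matrices (patients × genes), a bulk metabolite matrix
(patients × metabolites), cell type proportions, and per-patient metadata
(site, sex, Kellgren/Lawrence grade in {2, 3, 4}). All matrices share one
patient axis in identical order; (patient, cell type) combinations without
cells are `NA` rows excluded from that cell type's tests.

Preprocessing, in order, per feature: saturation at the 95th quantile
(values at or above the quantile are set to it, damping LC-MS and
pseudo-bulk outliers), highly-variable feature selection on the saturated
but unstandardized values, then centering/scaling to mean 0 and sample
standard deviation 1. Selecting features before standardization matters:
standardization equalizes all variances, which would make variance ranking
vacuous. Whether the upstream study selected features before or after
scaling is not something the pipeline can recover from its inputs; the
choice here is the only internally consistent order for a variance-based
selector.

The association test discretizes each metabolite at the 75th percentile of
its standardized abundance — patients at or above the threshold form
Group 1 — and applies a pooled two-sided two-sample t-test to every gene's
pseudo-bulk expression in every cell type. Discretization trades
information for robustness: untargeted LC-MS peak areas are noisy enough
that the relative order of samples is more trustworthy than their exact
values, and a rank-correlation alternative would let the many near-zero
observations dominate. The upper-quartile cut keeps both groups large
enough to compare (roughly 30 vs 89 patients in a 119-patient cohort).

## Tunable parameters

All constants live in `analysis_config()`:

| parameter | default | meaning |
|---|---|---|
| `saturation_quantile` | 0.95 | outlier cap per feature |
| `metabolite_split_quantile` | 0.75 | high/low abundance cut |
| `assoc_alpha` | 0.005 | nominal threshold declaring association |
| `de_alpha` | 0.05 | within-training DE feature selection |
| `n_hvg_genes`, `n_hvg_metabolites` | 2000, 1000 | features retained |
| `n_hub_genes`, `n_hub_metabolites` | 100, 50 | top-5% hub sets per cell type |
| `n_specific_hubs`, `n_pan_hubs` | 10, 50 | reported specific / pan hubs |
| `n_density_perms` | 200 | permutations in the density test |
| `rf_repeats_metabolite`, `rf_repeats_severity` | 100, 30 | repeated splits |
| `train_fraction` | 0.70 | train share per split |
| `link_accuracy_threshold` | 0.65 | reported accuracy needed for a link |
| `pan_link_min_celltypes` | 4 | links needed for a pan flag |
| `overlap_accuracy_threshold` | 0.6 | overlap-analysis accuracy filter |
| `min_group` | 5 | patients per side to run a test |

`assoc_alpha` is deliberately nominal rather than FDR-controlled: the
downstream consumers of the map are hub statistics and pathway filtering,
both of which aggregate over many pairs and are robust to the individual
false positives that a 0.005 threshold admits. BH-adjusted p-values are
computed within each cell type (the most conservative scope consistent
with per-cell-type reporting; the alternative global scope would couple
cell types through their p-value pools) and carried in the output for
users who want adjusted calls.

The significance operator is `p <= 0.005` everywhere; treating the
boundary case as significant is the reading consistent with the
discretization rule (`abundance >= threshold`), and exactly one operator
is used across all stages.

## Numerical choices

* Quantiles use linear interpolation of order statistics (type 7), the
  dominant default in scientific software; the same convention drives
  saturation, discretization and all examples in the tests.
* Scaling uses the sample (n−1) standard deviation. Zero-variance features
  are kept as all-zero columns and flagged, not dropped — matrix shapes
  stay stable across cell types.
* Zero pooled variance in a t-test yields (t = 0, p = 1, direction 0) with
  a flag instead of an error, so degenerate features never abort a
  90,000-test sweep.
* Metabolites whose split leaves fewer than `min_group = 5` patients on
  either side are skipped and logged; with fewer than 5 the t-test's
  degrees of freedom make results meaningless.
* All orderings that could tie (hub cutoffs, frequency rankings,
  enrichment tables) break ties lexicographically by entity id, making
  every output deterministic. Pan-cell-type ranks use average ranks on
  ties, and geometric-mean ties break by the smaller minimum rank, then id.
* The density permutation p-value is the fraction of draws *strictly*
  exceeding the observed density, with resolution 1/`n_density_perms`.
* The "median run" of an even number of severity repeats is the lower
  median (the 15th of 30 sorted accuracies), a deterministic choice.
* Every stochastic stage derives its own seed stream from the master seed
  via a string-keyed hash (`derive_seed()`), so enabling one feature never
  perturbs the draws of another; per-repeat RF seeds are master + repeat
  index.

## The repeated-split RF protocol

Metabolite attribution and severity classification share one protocol:
stratified 70/30 split (stratification preserves the 25/75 group ratio —
plain random splits occasionally produce single-class test sets),
differential-expression feature selection at `de_alpha` computed on the
training patients only, a randomized hyperparameter search (20 candidates
from trees {100, 300, 500} × depth {3, 5, 10, unbounded} × minimum leaf
{1, 3, 5}, scored by stratified cross-validation on the training set), a
final fit, and a balanced accuracy on the untouched test set. Feature
selection inside the split is what prevents leakage; the test suite
verifies that the protocol centers at balanced accuracy 0.5 on label-free
data.

The reported accuracy applies a branch rule: a 95% interval centered at
the mean accuracy with standard error `sqrt(a(1-a)/n_eff)`; if the lower
bound is below 0.5 the mean is reported, otherwise the median of the top
20 accuracies. `ci_n_eff` defaults to the number of repeats (an
SEM-style construction); the literal `n_eff = 1` reading is available as
a config option but makes the confident branch unreachable below a mean
accuracy of roughly 0.93, which is why it is not the default. The
binomial significance helper tests the raw correct count against chance
0.5 with an exact upper tail.

A cell-type-specific link additionally requires every other cell type to
fall below the threshold minus `specific_link_margin` (default 0); the
margin exists because "clearly better than every other cell type" admits
degrees, and the default is the weakest version of the rule.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes: 119
patients from 5 sites, 17 cell types whose Dirichlet proportion means are
dominated by lymphocytes and monocytes and anchored at 1.8% HSPC, 0.67%
megakaryocytes and 0.12% MSC, 2000 Gaussian baseline genes per cell type,
and 1000 log-normal metabolites (right-skewed like peak areas, so the
quartile split is non-degenerate). KL grades default to probabilities
(0.35, 0.40, 0.25) — a mid-heavy severity mix chosen once as realistic for
a treatment-seeking cohort, as the real distribution is not recoverable
from the inputs.

Planted structure and its rationale:

* **Free pairs** shift the gene's mean between the metabolite's high/low
  groups by ±`effect_size` (in noise-sd units), acting directly on the
  discretized grouping the test uses — this makes power analytically
  computable (a two-sample t-test at standardized shift δ with group
  sizes n/4 vs 3n/4).
* **Hub metabolites** receive `hub_fanout` shifted gene partners, each
  gene shifted once, so the mechanism above applies per partner.
* **Hub genes** are realized differently: their partner metabolites are
  constructed as correlated with the hub gene's expression (correlation
  chosen so the induced between-group expression difference matches
  `effect_size`, using E[z | top quartile] − E[z | rest] = 1.6949 for a
  standard normal). Stacking `hub_fanout` independent mean shifts on a
  single gene would inflate that gene's variance and dilute every
  per-partner effect after standardization — a planted hub that weakens
  itself. The correlation construction keeps the gene's marginal variance
  at baseline.
* **Severity signals**: selected metabolites shift on the log scale in the
  target KL grade; optionally, `n_kl_genes` genes shift by
  `kl_gene_effect` noise-sd units in one cell type for target-grade
  patients (the transcriptomic severity plant used by the recovery tests).
* A configurable fraction of planted pairs is written into synthetic
  pathway annotations (GMT + membership table), making them recoverable
  by the high-confidence filter; planted direction signs default to 72%
  negative (higher expression with lower abundance).

What the generator does **not** emulate: negative-binomial UMI counts or
any single-cell count model (cell-level draws are Gaussian around
pseudo-bulk means), per-cell-type variance structure (homoscedastic noise
throughout), LC-MS instrument drift, or batch structure beyond a site
label. Passing recovery tests therefore demonstrates that the statistics
are implemented correctly and calibrated under the stated model — not that
the model captures every failure mode of real data.

## Problem sizes in the test suite

The test suite runs the full protocol at reduced dimensions chosen to keep
a complete run within a desktop budget while leaving the statistical
conclusions intact: type-I calibration on 50,000 null pairs (120 patients,
500 genes × 100 metabolites, one cell type); parameter recovery at 200
patients × 300 genes × 100 metabolites × 3 cell types with planted effect
δ = 2; hub recovery over 20 seeds with fanout 50; permutation calibration
over 100 seeds × 200 permutations; leakage checks over 30 null
metabolites with 10 repeats and a 2-candidate/2-fold search. RF-heavy
tests scale down the hyperparameter search budget — the search space, not
the protocol, is reduced.

## Known limitations

* The pooled t-test assumes comparable within-group variances; Welch's
  form is available (`welch = TRUE`) but is not the default, matching
  common two-sample-t practice.
* Saturation introduces a small point mass at each feature's cap, which
  nudges the null type-I error slightly above nominal (measurably ~0.0054
  at the 0.005 threshold in the calibration tests — within three binomial
  standard errors, but systematic).
* The hypergeometric universes (hub-gene enrichment, metabolite overlap)
  default to the retained feature lists (2000 genes, 1000 metabolites);
  when the true background differs, pass it explicitly.
* Pathway annotations are inputs, not retrieved: the expected provenance
  is a gene-set GMT (e.g. exported from KEGG) and a pathway-metabolite
  membership table (e.g. from Metabolomics Workbench); no network access
  is performed anywhere.
* The pipeline models no ordinal structure across KL grades (each target
  grade is one-vs-rest) and performs no batch-effect correction — both are
  upstream concerns.
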