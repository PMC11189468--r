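---
title: "endosep: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{endosep: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`endosep` packages an endotype-discovery and mortality-prognosis workflow
for multi-site bulk RNA-seq sepsis cohorts. This vignette records the
statistical models behind each stage, the parameters that matter and why
their defaults are what they are, the places where the design was genuinely
open and how we resolved them, and what the bundled synthetic cohort can and
cannot demonstrate.

## The synthetic cohort model

Patient-level sepsis transcriptomes with outcomes are access-restricted, so
the package's testbed is a generative model (`sim_config()`,
`simulate_cohort()`) with known ground truth. Its defaults are the study
conditions every test and the acceptance script run under:

* **Cohort.** 500 patients from 3 sites (equal thirds); site effects enter
  only through sequencing depth (per-site library-size factors around
  `exp(±0.15)`), reflecting a cohort whose preprocessed expression shows no
  site bias. An optional `site_batch_log2_shift` knob exists for robustness
  experiments. Age and sex are generated independently of mortality.
* **Endotypes.** Four latent classes with proportions 0.2/0.2/0.2/0.4 and
  28-day mortalities 0.22/0.22/0.20/0.11 — three smaller high-mortality
  endotypes and one large low-mortality endotype. Each endotype up-regulates
  its own 50-gene module by 1.0 log2 unit (interferon-like,
  inflammation-like, heme-like, immunosuppression-like in spirit). Module
  effect sizes are not reported for real cohorts; 1.0 log2 was chosen once
  as a moderate, realistic shift that is neither trivially separable nor
  undetectable at n = 500.
* **Counts.** Gene `g`, patient `j` draws NB with mean
  `s_j · μ_g · 2^Δ_gj` and dispersion `α(μ) = a0 + a1/μ`
  (defaults `a0 = 0.05`, `a1 = 2`, typical of bulk RNA-seq); library sizes
  are lognormal (`meanlog = log(5e6)`, `sdlog = 0.3`). 300 genes are pegged
  below the mean-CPM-10 filter line (they are specified in final CPM units
  so the invariant holds for any cohort size), 100 genes sit on chromosomes
  X/Y (Y genes silenced in females), and a slice of the low-expression
  genes carries no chromosome annotation, exercising all three filter
  rules.
* **Mortality.** A latent standard-normal risk score `u_j` drives death:
  `logit P(death) = β0_k + γ·u_j`, with `β0_k` solved numerically
  (Gaussian quadrature + root finding) so each endotype's marginal
  mortality equals its target exactly. The slope default `γ = 1.5` puts the
  oracle risk AUROC near 0.82, so a noisy gene-panel readout of `u` lands
  around 0.8 — comfortably above the clinical-score target below, the regime
  the pipeline is meant to demonstrate. 25 prognostic genes couple to `u`
  with ±0.8 log2 per unit (half up, half down in non-survivors).
* **Clinical score.** A 0–3 integer severity score is a discretized noisy
  monotone transform of the true death probability, calibrated against the
  *realized* deaths so its empirical AUROC matches
  `clinical_score_auroc_target` (default 0.72). Because deaths are
  stochastic given risk, targets above what true risk can discriminate are
  unreachable by adding noise; the calibration path therefore extends in the
  other direction by mixing outcome signal into the latent score. This is a
  simulation device: the target is a property of the score–outcome pair,
  not of the latent risk.

All draws flow from one RNG stream seeded by `config$seed`; identical
configurations are byte-identical.

What the generator does *not* emulate: count over-dispersion beyond the
two-parameter trend, gene–gene correlation outside the planted modules,
batch/library-prep artefacts, censoring or missing outcomes, and pathogen
etiology. Tests passing on this cohort show the pipeline's statistics are
correct and well calibrated under its assumptions — not that real sepsis
cohorts satisfy those assumptions.

## Preprocessing

Filtering retains genes with **mean CPM ≥ 10** (inclusive; CPM computed on
pre-filter library totals), autosomal location, and a known annotation. The
mean-across-patients reading of the CPM rule is the common practice where a
per-sample variant is not specified; both the threshold and the rule are
arguments to `filter_genes()`.

Size factors are **median-of-ratios**: `s_j = median_g counts_gj / geomean_g`
over reference genes with strictly positive counts in all patients,
rescaled to geometric mean 1. A `pseudo_reference` flag (genes positive in
≥ 90% of patients) covers sparse data. The unit test suite cross-checks the
estimator against DESeq2's reference implementation.

The dispersion–mean trend is fitted on normalized counts by
method-of-moments per gene (`α̂ = max((v − μ)/μ², 1e-8)`, genes with
normalized mean ≥ 1), then a robust `α = a0 + a1/μ` fit that iteratively
drops genes beyond 2 MADs of the residual; coefficients are clipped at 0,
and an all-at-floor degenerate input falls back to `(0.01, 1)` with a
warning. The closed-form VST

$$u(x) = \log_2 \frac{1 + a_1 + 2 a_0 x + 2\sqrt{a_0 x (1 + a_1 + a_0 x)}}{4 a_0}$$

is pinned explicitly (strictly increasing, `u(0)` finite, `u(x) − log2(x)`
constant for large `x`) so results are reproducible without reference to
any particular implementation's internals. On default synthetic data the
ratio of per-gene sd between top and bottom mean-deciles drops from ≈ 40
before stabilization to ≈ 1.1 after.

## The mapper construction

The mapper stage runs on the 1000 most-variable VST genes (configurable),
with patient distance `d_ij = 1 − r_ij` (Pearson). Note correlation is
shift-invariant: endotypes must differ in profile *shape*, which planted
modules guarantee.

**Lenses.** The platform lenses that inspired this stage are proprietary,
so a deterministic surrogate with the same intent (local-neighbourhood
geometry) is pinned: the two leading nontrivial eigenvectors of the
symmetric normalized Laplacian of the k-NN graph (`k = 15`, unit weights),
min–max scaled to [0, 1], eigenvector signs anchored to the
smallest-id patient. Two departures from a textbook mutual k-NN graph were
forced by the data:

* a *mutual* k-NN graph fragments into the endotype blobs themselves (the
  largest component can hold < 50% of patients), leaving most of the cohort
  without coordinates. The graph is therefore augmented with the minimum
  spanning tree of the distance matrix — the standard connectivity repair in
  manifold learning — which adds only `n − 1` short edges and leaves local
  geometry intact;
* neighbours tied at the k-th distance are all included, so duplicated
  patients receive identical coordinates.

**Cover.** Per axis, `R = 15` intervals with evenly spaced centers and
common length `range·(1 + g)/R` (`g = 0.35`), clipped to the data range,
half-open except the last; 2-D bins are Cartesian products. Adjacent
intervals overlap by `g·range/R`, which is what lets groups share patients.

**Clustering and graph.** Within each bin, single-linkage clustering is cut
at the first empty bar (after the first occupied bar) of a 10-bin histogram
of merge heights — the classic mapper gap heuristic; no gap, singleton bins
and all-equal distances give one cluster. Clusters of ≥ 2 patients become
nodes; nodes sharing patients are joined by edges weighted with the shared
count.

**Groups.** Node communities from deterministic greedy modularity
maximization (nodes ordered by descending size, id tiebreak) are the
endotype groups; a patient in nodes of more than one community is `shared`.
If the shared fraction exceeds the 10% cap, the cover is re-searched over
`R ∈ {10, 15, 20, 25} × g ∈ {0.20, 0.30, 0.35, 0.40}`, keeping the setting
with the most groups holding ≥ 5% of patients subject to the cap (the grid
and the 5% floor are this package's own policy; the upstream description
fixes only the cap itself). Groups with fewer than 10 deaths merge pairwise
with an adjacent below-threshold group, and final labels `t1..tK` descend
by group mortality. On default synthetic cohorts the exclusive labels
recover the planted endotypes with adjusted Rand index ≈ 0.9 (the
acceptance suite requires median ≥ 0.6 over 10 seeds).

## Differential expression and clinical comparisons

Welch's two-sample t-test per gene (closed form, vectorized;
Welch–Satterthwaite degrees of freedom; a zero pooled standard error
returns `t = 0, p = 1` with a warning), BH adjustment across all genes of
the contrast (the multiple-testing family is one contrast, not the union of
contrasts), and L2FC defined as the difference of group means on the VST
scale — the VST scale is log2-like, so mean differences are log2 fold
changes; the sign convention is case minus control (died minus survived).
Between-group contrasts use only patients exclusive to a single group;
unions such as `t1+t2+t3` are merged before testing. Patients with missing
mortality are dropped. Clinical features are compared with `stats::aov`
across groups and Welch tests for requested pairs, restricted to features
observed in at least two patients of every group.

## Prognostic modelling

* **mRMR.** Relevance is the two-group ANOVA F statistic, z-scored across
  the candidate pool once at the start (making it commensurable with the
  correlation-scale redundancy); redundancy is the mean |Pearson r| with the
  already-selected genes; score = relevance_z − redundancy, greedy forward
  selection, gene-id tiebreaks.
* **Cross-validation.** 10 repeats × 10 stratified folds. Fold membership
  is derived from an FNV-1a hash of patient id, seed and repeat — fully
  deterministic, invariant to row order, and stable under subsetting, which
  is what lets the gene panel and the clinical comparator share identical
  folds, and per-group models remain comparable.
* **Per-fold model.** Ridge logistic regression by Newton iterations
  (penalty `0.5·||β||²` excluding the intercept, features standardized on
  the training fold only, 1000-iteration cap). The ridge-with-unit-strength
  choice mirrors the default of the mainstream logistic-regression tooling
  the workflow is modelled on; it is implemented directly because the panel
  comparison needs single-feature models and a fixed penalty, and is
  cross-checked against `glm()` in the unpenalized limit.
* **Panel sizing.** The step-up rule evaluates the first `n` ranked genes
  for `n = 1..max_n` and applies a one-standard-error rule: the smallest `n`
  whose mean AUROC is within `sd(argmax)/sqrt(repeats·folds)` of the best
  mean. The upstream description reports only that step-up "resulted" in a
  panel; the one-SE rule is our explicit, conventional instantiation.
* **Model inputs** are per-patient VST expression values of the selected
  genes. A mortality-based per-patient fold-change transform is a
  conceivable alternative reading of the source material; expression is
  pinned as the primary definition.

**Caveat — selection leakage.** Ranking genes by mRMR on the full cohort
and then cross-validating panels from that ranking re-uses the data: the
tail of a top-50 list selected from thousands of genes is enriched for
chance in-sample association, which measurably inflates the CV AUROC curve
as panels grow and can push the one-SE rule toward larger panels. The
package follows the published workflow (rank once, then CV), but the
acceptance suite demonstrates the effect and evaluates panel-size recovery
with an a priori candidate pool, where the ranked tail is genuinely null.

## Enrichment

Preranked GSEA on L2FC-ranked genes (decreasing; between-group contrasts
keep only `p_adjusted ≤ 0.05` genes — inclusive boundary — while
within-group contrasts use all genes). The running sum rises by
`|stat|^p / Σ_hits |stat|^p` at set genes (`p = 1`) and falls by
`1/(N − N_hits)` elsewhere; the ES is the signed maximum deviation
(magnitude ties resolve positive, with a `1e-12` tolerance guarding
rounding). The null is **gene permutation** — random same-size draws from
the ranked list — because the input is a precomputed ranking and phenotype
permutation is unavailable at this stage. NES divides by the mean |null ES|
of matching sign; p-values use the add-one estimator over matching-sign
nulls; BH runs across all size-eligible sets before the `p_cutoff` filter.
With `n_perm` permutations the smallest attainable p is ≈ `2/n_perm`, so
small-FDR claims need permutation counts sized to the collection. Licensed
pathway collections are not redistributed; `synthetic_gene_sets()` builds a
Hallmark-like synthetic collection (flagged as synthetic in name and
description) whose first five sets are the planted endotype modules and
prognostic genes, and any real GMT can be supplied instead.

## Pipeline, reporting and problem sizes

`run_pipeline()` chains the stages in a fixed order, logs per-stage counts
(genes filtered, patients dropped, groups found), wraps stage errors with
the stage name, and writes a bundle of TSVs, model-report JSONs, the mapper
graph as GraphML + JSON, heatmap row orders (Manhattan distance with
McQuitty or Ward linkage), and a manifest (configuration, seed, package and
R versions, and a config hash that excludes the output directory) from
which a byte-identical rerun can be launched. Within the pipeline, mRMR
candidates are the BH-significant genes of the full-cohort contrast,
falling back to `p ≤ 0.05` and then to all genes when fewer than the
requested 50 are available.

Test-suite problem sizes were chosen to exercise the study-scale defaults
where the claim depends on them (500 patients × ~3400 genes for recovery,
calibration and discrimination checks; 10–20 seeds per property) and
reduced cohorts (120–150 patients, ~500 genes) where only correctness of
the mechanics is at stake.

## Known limitations

* The lens surrogate is *a* neighbourhood embedding, not the proprietary
  one it stands in for; group boundaries on real data will differ from any
  other mapper implementation even at identical `(R, g)`.
* Greedy modularity can split one diffuse endotype into several adjacent
  groups (the merge step heals this only for low-mortality groups, as
  specified); the group count is therefore an upper bound on distinct
  biology.
* The NB-VST assumes the two-parameter dispersion trend; strongly bimodal
  or zero-inflated genes violate it.
* CV AUROC under rank-once-then-CV retains the selection optimism discussed
  above; an outer selection loop would remove it at the cost of departing
  from the workflow being reproduced.
* `clinical_compare` treats features as independent; no multiplicity
  control is applied across features.
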