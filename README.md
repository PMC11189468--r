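# endosep

Endotype discovery and mortality prognosis from sepsis blood transcriptomics.

Sepsis is a heterogeneous syndrome: patients arriving with the same clinical
picture can carry very different underlying immune states (endotypes) with
very different risks of death. `endosep` implements, as a tested and
reusable R pipeline, an analysis strategy for multi-site bulk RNA-seq sepsis
cohorts that

1. **preprocesses** gene-level counts — mean-CPM ≥ 10 filter, removal of
   sex-linked (chromosome X/Y) and unannotated genes, median-of-ratios
   (MoR) size factors, and a closed-form negative-binomial
   variance-stabilizing transformation (VST)
   `u(x) = log2((1 + a1 + 2·a0·x + 2·sqrt(a0·x·(1 + a1 + a0·x))) / (4·a0))`
   with the dispersion–mean trend `α(μ) = a0 + a1/μ` fitted robustly from
   the data;
2. **stratifies patients** with a from-scratch mapper (topological data
   analysis) construction: correlation distance `d = 1 − r` between patient
   expression profiles, two spectral *neighborhood* lenses (leading
   nontrivial eigenvectors of the normalized Laplacian of an MST-augmented
   mutual k-NN graph), an overlapping 2-D cover (resolution `R`, gain `g`),
   single-linkage clustering within each bin, and a node graph whose
   communities become soft endotype groups — with at most 10% of patients
   allowed to be shared between groups, and data-driven merging of
   low-mortality groups;
3. **tests differential expression** gene-wise with Welch's t-test and
   Benjamini–Hochberg FDR control, within groups (died vs survived) and
   between groups (exclusive members only), plus ANOVA/Welch comparisons of
   clinical laboratory features across groups;
4. **builds prognostic models**: minimum-redundancy–maximum-relevance
   (mRMR) gene ranking (F-statistic relevance, mean |Pearson r| redundancy),
   step-up panel sizing under 10×10 repeated stratified cross-validated
   AUROC of a ridge logistic model, and head-to-head comparison against a
   0–3 bedside severity score (qSOFA-like) on identical fold assignments;
5. **runs preranked gene-set enrichment**: weighted running-sum enrichment
   scores on L2FC-ranked genes, gene-permutation normalized enrichment
   scores (NES) and p-values, GMT input/output.

Because the motivating patient-level data are access-restricted, the package
ships a first-class **synthetic cohort generator** (`simulate_cohort()`)
with known ground truth — four latent endotypes with mortalities
22/22/20/11%, endotype-specific gene modules, mortality-coupled prognostic
genes, negative-binomial counts with a dispersion–mean trend, lognormal
library sizes, and a clinical score calibrated to a target AUROC (default
0.72) — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(endosep)

cohort <- simulate_cohort(sim_config(seed = 1))    # 3400 genes x 500 patients
prep   <- preprocess_counts(cohort$counts)
prep$filter_log
#>   criterion          n
#> 1 low_expression   321
#> 2 sex_linked       100
#> 3 unannotated       39
#> 4 retained        2982

groups <- mapper_endotypes(prep$expr, mapper_config(), cohort$cohort)
groups
#> <endotype_groups> 7 groups, 498 patients, shared fraction 0.018
#>   t1: 19 patients, mortality 0.26
#>   t2: 4 patients, mortality 0.25
#>   t3: 100 patients, mortality 0.22
#>   ...
#>   t7: 204 patients, mortality 0.11
```

Groups are labelled `t1..tK` by descending 28-day mortality; 1.8% of
patients sit in more than one group, inside the 10% sharing cap. The
high-mortality groups (~22–26%) and the large low-mortality group (11%)
reflect the four planted endotypes.

```r
X  <- t(prep$expr)
y  <- cohort$cohort$death28[match(rownames(X), cohort$cohort$patient_id)]
panel  <- mrmr_rank(X, y, m = 50)                  # mRMR top 50
clin   <- cohort$cohort$qsofa[match(rownames(X), cohort$cohort$patient_id)]
report <- compare_with_clinical_score(X, y, head(panel$gene_id, 8), clin, seed = 1)
report
#> <model_report> full cohort: 8 features, AUROC 0.827 +/- 0.080 (n = 500)
#>   clinical score: AUROC 0.730 +/- 0.093
```

The eight-transcript panel clearly outperforms the clinical severity score
(cross-validated AUROC 0.83 vs 0.73) under identical, hash-derived fold
assignments. `tidy()`/`glance()` turn reports into tibbles, and
`autoplot()` draws the step-up curve, fold-score boxplots, or the mapper
graph. `run_pipeline(pipeline_config(...))` chains all stages — simulate or
ingest, preprocess, DE, models, mapper groups, per-group models, enrichment,
clinical comparisons — and writes a TSV/JSON/GraphML report bundle with a
reproducibility manifest.

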