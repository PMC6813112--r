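# tnfblood

Analysis workflow for whole-blood molecular correlates of anti-TNF
treatment and response in rheumatoid arthritis (RA).

About a third of RA patients fail to respond to TNF-inhibitor therapy, and
no baseline marker reliably predicts response. This package implements, as
a tested R pipeline, the analysis design of a two-cohort whole-blood
study: patients profiled at baseline (BL) and after three months (MO3) of
anti-TNF treatment, classified as EULAR good responders (GR) or
non-responders (NR) from DAS28-CRP, and measured by bulk RNA-seq, plasma
proteomics, and complete blood counts (CBC). It answers three questions:
what treatment does to whole-blood expression (a reproducible neutrophil
reduction), what distinguishes responders at baseline (an innate/adaptive
cell-balance shift), and whether routine CBC ratios carry the same signal
at registry scale (logistic models on the neutrophil-to-lymphocyte ratio).

## What is implemented

* **Synthetic cohorts with ground truth** — negative-binomial counts as
  cell-type mixtures; treatment multiplies the neutrophil fraction at MO3
  by 0.87; responders carry a baseline innate excess; CBC and DAS28-CRP
  components derive from the same truth (`generate_reference`,
  `generate_cohort`, `generate_cbc_population`, `generate_protein_matrix`).
* **Differential expression** — log2-CPM with mean–variance precision
  weights, per-feature weighted least squares, empirical-Bayes moderated
  t-statistics (method-of-moments prior, `(d0·s0² + d·s²)/(d0+d)` posterior
  variances), Benjamini–Hochberg FDR (`run_differential` and the
  underlying `log_cpm`, `voom_weights`, `fit_weighted_lm`,
  `ebayes_moderate`, `bh_fdr`).
* **Cross-cohort concordance** — Spearman correlation of effect profiles
  with permutation nulls (sign-flip within subject for paired contrasts),
  and top-variable-gene restriction (`permutation_concordance`,
  `top_variable_subset`).
* **Cell-type analysis** — log2 specificity scores versus the mean of the
  other cell types, disjoint marker sets, effect-vs-specificity
  correlation, set-level mean effects with permutation p-values, and the
  innate/adaptive compartment summary (`specificity_scores`,
  `build_marker_sets`, `set_effect_with_permutation`,
  `innate_adaptive_summary`).
* **Clinical statistics** — DAS28-CRP scoring, the EULAR response matrix,
  the 800 ng/mL drug-level exclusion for non-responders, and Table-1-style
  summaries with Wilcoxon / Yates chi-square tests (`das28_crp`,
  `eular_classify`, `cohort_filter`, `table1_summary`).
* **CBC response models** — NLR/NWR/LWR log-ratios, paired BL→MO3 ratio
  change with t-intervals, and unadjusted/adjusted logistic models with
  Wald odds-ratio intervals (`cbc_log_ratios`, `paired_ratio_change`,
  `logistic_fit`, `response_model`, `genotype_association`).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on synthetic
study-sized cohorts (C1: 19 GR + 21 NR; C2: 21 GR + 15 NR; 600 genes, half
of them cell-type markers):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_treatment_effects.R
Rscript analysis/03_baseline_response.R
Rscript analysis/04_cbc_response_models.R
Rscript analysis/05_clinical_tables.R
```

`02_treatment_effects.R` prints (seed 1):

```
C1: 600 genes tested, 89 at FDR < 0.05 (31 down at MO3)
C2: 600 genes tested, 72 at FDR < 0.05 (25 down at MO3)
cross-cohort MO3-BL concordance: rho = 0.585, permutation p = 0.000999 (1000 perms)
C1: effect vs neutrophil specificity rho = -0.696
C2: effect vs neutrophil specificity rho = -0.657
C1: neutrophil/WBC ratio at MO3 = 87.1% of baseline [85.5%, 88.7%], p = 2.66e-18
C2: neutrophil/WBC ratio at MO3 = 86.8% of baseline [84.8%, 88.7%], p = 6.07e-15
```

Reading this: both cohorts show a replicated month-3 signature (high
cross-cohort rank correlation, rarely matched under label permutation);
genes specific to neutrophils are the ones going down (negative
effect-vs-specificity correlation); and the paired CBC estimator recovers
the designed neutrophil/WBC reduction to 87% of baseline. The baseline
script then shows both innate marker sets up and all four adaptive sets
down in responders (`innate-up`, each set's permutation p ≤ 0.015), and
the CBC script recovers the designed odds ratio of good/moderate response
per log-NLR unit (designed 1.20; fitted 1.36 with Wald CI [1.14, 1.61] at
n = 1962).

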