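# grsscnv

Integrated analysis of common SNPs and copy-number variants (CNVs) for body
mass index (BMI) and obesity risk.

## The problem

Common SNPs validated for BMI each move the phenotype by only 0.06–0.39
kg/m² per risk allele, and in aggregate explain a few percent of its
variance; rare CNVs have been proposed to carry part of the remainder.
Testing both classes jointly requires machinery that is usually scattered
across tools: risk-score construction from imputed genotypes, consensus
CNV calling across multiple callers, catalog matching, covariate-adjusted
regression, and ROC-based evaluation of clinical prediction. `grsscnv`
packages that pipeline for R users — geneticists and statisticians working
with cohort genotype + CNV-call + phenotype data — together with a
calibrated simulator, so the whole analysis is testable without
access-restricted cohort data.

## What it computes

**Genetic risk sum scores.** For subject *j* over *n* catalog SNPs with
risk-allele dosages *p<sub>ij</sub>* ∈ [0, 2] and weights *β<sub>i</sub>*:

    GRSS_j = ( Σ_i β_i · p_ij ) / D

with *β* = 1 (count) or the published per-allele effect (weighted), and
*D* = 2*n* (hard-call methods) or *n* (probability methods). Six methods:
{count, weighted} × {proxy hard calls, imputed hard calls, imputation
probabilities}. Methods are compared by
*z* = (ES<sub>a</sub> − ES<sub>b</sub>) / √(SE<sub>a</sub>² + SE<sub>b</sub>²).

**CNV pipeline.** Confidence filter (Log Bayes Factor ≥ 10) → consensus
events supported by ≥ 2 callers at ≥ 50% reciprocal overlap → removal of
artifact-prone regions → catalog matching at ≥ 40% reciprocal overlap →
common/rare split at 1% carrier frequency → per-region carrier codings,
aggregate count scores (optionally events ≥ 100 kb) and genome-wide rare
burden.

**Models.** OLS for BMI and logistic regression for cumulative obesity
classes (BMI ≥ 25/30/35/40), centered predictors, interaction scan at
Bonferroni α = 0.002, nested F tests, incremental R², and ROC/AUC with
DeLong intervals and paired curve tests for nested models
(covariates → + SNP-GRSS → + CNV).

See `vignette("integrated-snp-cnv-bmi")` for the full methods account.

## Worked example

One end-to-end run on a synthetic cohort at study scale (n = 2348, 32
catalog SNPs, 84 CNV regions):

```r
library(grsscnv)
res <- run_pipeline(default_config(seed = 3))

res$association$delta_r2
#>   step     delta_r2 cumulative_r2
#> 1    2 2.774436e-02     0.1104525
#> 2    3 8.793021e-05     0.1105405

res$prediction[, c("outcome", "model", "auc", "delta_auc", "pct_delta_auc")]
#>                 outcome      model       auc     delta_auc pct_delta_auc
#> overweight.1 overweight covariates 0.6580071            NA            NA
#> overweight.2 overweight      +GRSS 0.6710870  0.0130798699    1.98780071
#> overweight.3 overweight       +CNV 0.6708386 -0.0002483907   -0.03701319
#> obese_I.1       obese_I covariates 0.6235795            NA            NA
#> obese_I.2       obese_I      +GRSS 0.6575641  0.0339845900    5.44992104
#> obese_I.3       obese_I       +CNV 0.6579468  0.0003827488    0.05820707
#> obese_II.1     obese_II covariates 0.6716885            NA            NA
#> obese_II.2     obese_II      +GRSS 0.7233623  0.0516737820    7.69311709
#> obese_II.3     obese_II       +CNV 0.7235495  0.0001871962    0.02587862
#> obese_III.1   obese_III covariates 0.6975262            NA            NA
#> obese_III.2   obese_III      +GRSS 0.7122785  0.0147522393    2.11493683
#> obese_III.3   obese_III       +CNV 0.7138354  0.0015569139    0.21858218
```

Reading this: adding the weighted probability SNP-GRSS to the covariate
model explains an additional 2.77% of BMI variance (the generator's true
share is 3.1%, attenuated by imputation quality and phenotype QC), the
deletion-carrier term adds ~0.01%, and the combined model reaches R² =
0.111. In prediction, the GRSS lifts the covariate-only AUC for every
obesity class (e.g. overweight 0.658 → 0.671, +1.99%), while the CNV
terms add little — the expected behaviour when a single small-effect
deletion is the only real CNV signal.

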