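---
title: "Integrated SNP risk scores and CNV analysis for BMI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated SNP risk scores and CNV analysis for BMI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsscnv)
```

## The analysis this package implements

Body mass index is a model polygenic trait: a few dozen common SNPs show
robustly replicated association, each with a small per-allele effect
(roughly 0.06–0.39 kg/m² among the validated loci), and a growing list of
copy-number variants (CNVs) has been proposed to contribute, mostly at low
frequency. `grsscnv` implements a joint analysis of both classes of
variation in a single cohort:

1. **Genetic risk sum scores (GRSS).** Per-subject aggregates of
   risk-allele dosages over a catalog of validated SNPs, under six methods:
   count (unit weights) versus weighted (per-allele effect sizes), crossed
   with three genotype sources — proxy markers (hard calls on correlated
   array SNPs standing in for untyped loci), imputed hard calls, and
   imputation-probability triples scored at their expected risk-allele
   count.
2. **CNV consensus and aggregation.** Per-caller CNV calls are filtered by
   confidence (Log Bayes Factor ≥ 10), merged into consensus events
   requiring support from at least two callers at ≥ 50% reciprocal
   overlap, cleared of artifact-prone regions, matched against a
   literature catalog at ≥ 40% reciprocal overlap, split into common
   (carrier frequency ≥ 1%) and rare classes, and summarized as per-region
   carrier indicators, aggregate count scores (optionally restricted to
   events ≥ 100 kb) and a genome-wide rare burden.
3. **Association models.** Ordinary least squares for BMI and logistic
   regression for cumulative obesity classes (thresholds 25/30/35/40
   kg/m²), with centered predictors, a fixed covariate set (ancestry PCs,
   sex, age, alcohol and nicotine dependence), an interaction scan at a
   Bonferroni threshold of 0.002, nested-model F tests and incremental R²
   attribution.
4. **Risk prediction.** ROC/AUC evaluation of the nested models
   (covariates → + SNP-GRSS → + CNV terms) per obesity class, with
   DeLong variances, Wald 95% intervals, a paired test for the AUC change
   and a ΔAUC / %ΔAUC report.

Because cohort genotype–phenotype data of this kind are access-restricted,
the package ships a calibrated synthetic cohort generator so that every
stage is exercised end to end, and so that estimator behaviour can be
checked against known truth.

## The score model

For subject $j$, a score over $n$ SNPs with per-SNP weights $\beta_i$ and
risk-allele dosages $p_{ij} \in [0,2]$ is

$$\mathrm{GRSS}_j = \frac{1}{D}\sum_{i=1}^{n} \beta_i \, p_{ij},$$

with $\beta_i = 1$ for count scores and $\beta_i$ the published per-allele
effect (kg/m²) for weighted scores. Hard-call methods use the per-allele
denominator $D = 2n$; probability methods use the per-SNP denominator
$D = n$. The denominator is a pure change of scale — t statistics and
incremental R² downstream are invariant to it — and both conventions are
selectable. Missing genotypes are scored at their Hardy–Weinberg
expectation $2\hat f$ using the sample allele frequency of the analyzed
subjects. Two score methods are compared by
$z = (ES_a - ES_b)/\sqrt{SE_a^2 + SE_b^2}$ with a standard-normal p-value.

Allele harmonization matches catalog risk/other alleles against VCF
REF/ALT, attempting a strand flip when the direct comparison fails;
palindromic A/T and C/G sites are flagged and excluded unless explicitly
allowed, since strand cannot disambiguate them.

## The synthetic cohort generator

The generator produces exactly the statistical structure the estimators
assume, nothing more:

- **Genotypes.** Each SNP's risk dosage is Binomial(2, $f_i$) per subject
  (Hardy–Weinberg), loci independent (linkage equilibrium). The default
  catalog is 32 SNPs with frequencies evenly spread over (0.1, 0.9) —
  per-locus frequencies of the real validated set live in supplementary
  material we do not reproduce — and effects spread over 0.06–0.39 kg/m².
- **Imputation-probability triples.** A Gaussian signal $s = g +
  N(0,\tau^2)$ is observed and converted to the posterior over $g$ under
  the Hardy–Weinberg prior. $\tau$ is calibrated per SNP by root-finding
  so the expected info statistic (dosage variance over $2f(1-f)$) equals
  the target quality. A posterior construction was chosen over a
  Dirichlet perturbation centered on the truth because the posterior mean
  is guaranteed to shrink toward the frequency expectation (info ≤ 1),
  which is what real imputation dosages do; a Dirichlet centered on the
  truth adds symmetric noise and can inflate the dosage variance instead.
  Quality 1 yields exactly degenerate triples, making probability scores
  equal hard-call scores — a property the tests assert exactly. The
  default quality is 0.95, typical of well-imputed common variants and
  above the 0.8 floor used when selecting imputed SNPs.
- **Proxy markers.** Each of the two haplotype alleles is copied with a
  flip probability solved so the squared allelic (hence dosage)
  correlation equals the target r² (default 0.8); one catalog SNP has no
  adequate proxy by default, so proxy scores cover 31 of 32 loci.
- **CNV calls.** 84 planted loci emulate a literature catalog: three
  common loci (carrier frequencies 16.9%, 1.2%, 7.7%; only the 21-kb
  deletion at 16.9% carries a BMI effect by default, matching the single
  replicated region) and 81 rare loci. Three caller profiles differ in
  sensitivity (0.90–0.95), boundary jitter (250–600 bp SD), false-call
  rate (0.20–0.30 spurious calls per subject, placed uniformly off the
  planted loci) and confidence: one caller emits no Log Bayes Factor and
  passes the confidence filter flagged, the other two draw true-call LBFs
  well above and spurious LBFs mostly below the threshold of 10.
- **Phenotype.** $\mathrm{BMI} = \mu + c_{cov}\,\ell_{cov} + c_g \sum_i
  \beta_i g_i + c_{cnv}\,\ell_{cnv} + \varepsilon$. Under HWE/LE the raw
  genetic variance is $\sum_i 2 f_i (1-f_i) \beta_i^2$; the covariate
  predictor's variance (sex Bernoulli, age Normal, dependence indicators
  with sex-dependent rates, standard-normal PCs, two interaction terms)
  is computed analytically from the design marginals, and the CNV term's
  from carrier frequencies. Each scale $c$ is solved so the component's
  share of total variance ($\sigma_\varepsilon^2$ divided by the residual
  fraction) equals its target exactly in expectation; a 10⁵-subject check
  in the test suite verifies each share within 0.005. Defaults: intercept
  27.63 kg/m², residual SD 5.6 kg/m² (total SD ≈ 6), fractions 8.3%
  (covariates), 3.1% (GRSS), 0.1% (CNV deletion), n = 2348 split 1850/498
  across two ancestry labels. Height is drawn per sex and weight
  back-computed, so the QC stage can recompute BMI from its inputs.

What the generator does **not** emulate: LD beyond single proxy pairs,
haplotype blocks, array-intensity artifacts, genomic waves, skewed BMI
distributions, or ancestry-specific allele-frequency differences (the
ancestry label is a bookkeeping covariate by default). Passing recovery
tests therefore show estimator correctness under the model's assumptions,
not robustness to real-data violations of them.

## Phenotype QC and bodyweight classes

BMI is always recomputed as weight/height²; a supplied BMI differing by
more than 0.1 kg/m² is logged. Exclusion bounds follow the strict
inequalities of the rule text — height outside [1.4, 2.0] m, weight
outside [38, 166] kg, BMI outside [14.5, 60] kg/m² — so boundary values
are retained, and each removal is logged with its triggering rule.
Bodyweight classes nest (overweight ⊇ obese I ⊇ II ⊇ III) and cumulative
indicators are exposed for the logistic models.

One consequence of a Gaussian phenotype with total SD ≈ 6 is that range QC
removes roughly 1–2% of simulated subjects *selected on the outcome*,
which slightly truncates the phenotypic variance. Variance-fraction
recovery (`variance_recovery_study()`) is therefore assessed on the full
generated cohort, the population the calibration refers to; the QC stage
is exercised separately. On real self-reported data the same bounds
remove data-entry errors rather than genuine tail observations, so this
truncation is a generator artifact, not an analysis property.

## CNV pipeline conventions

All intervals are 0-based half-open, in BED fashion; VCF positions are
converted on read. Abutting intervals do not overlap, and the exclusion
filter removes events at ≥ 1 bp overlap (the artifact regions were removed
wholesale in the source analysis, without a fraction).

Consensus grouping builds connected components of the pairwise
reciprocal-overlap relation within sample, chromosome and state; a
component with ≥ 2 distinct callers emits one event. The consensus
interval is the **intersection** of supporters (conservative); the
boundary **envelope** is their union and is what the ≥ 100-kb length
filter tests, since larger calls span more probes. In the degenerate case
of a chained component whose global intersection is empty, the widest
cross-caller pairwise intersection is used. The construction is invariant
to caller and call order, and removing a caller can never enlarge the
consensus set — both properties are asserted in tests.

Catalog matching is reciprocal at 40% of *both* the event and the catalog
interval, consistent with the 50% reciprocal consensus rule; the phrase
"shared at least 40% overlap" is directionally ambiguous, so one-way-only
candidates are counted and reported. An event is assigned to at most one
region (best minimum fraction; ties to the smaller catalog interval, then
the label). Carrier coding is binary per region per subject, with
deletions and duplications as separate regions.

## Association and prediction choices

Predictor entry follows a fixed, configured order (covariates → GRSS →
CNV), matching the nested-model presentation of the analysis this package
reproduces; there is no automatic variable deletion. The interaction scan
tests each candidate one at a time against the base model and admits
terms at p < 0.002 jointly into the final model; its type-I behaviour at
the nominal level is verified by simulation. Nested models are compared
by the RSS-based F statistic, which satisfies
$F = (\Delta R^2/q)\,/\,((1-R^2_{full})/(n-p_{full}))$ to numerical
precision. The 2×2 descriptive tests use the cross-product chi-square
without continuity correction. A variance-inflation diagnostic is
available for correlated predictors (e.g. a SNP tagging a CNV).

AUC is the midrank Mann–Whitney estimate; variance, Wald CIs and the
paired comparison between nested models use the DeLong placement
estimator (via pROC), replacing the web-based curve-comparison service
used in the original analysis with a fully offline equivalent of the same
null and asymptotics. The %ΔAUC denominator is the previous (smaller)
model's AUC. The "significance of model" column tests AUC = 0.5; with
degenerate (constant) scores the p-value is reported as 1.

## Numerical and degenerate-input choices

- GP triples must sum to within [0.99, 1.01] before renormalization;
  missing genotypes are flagged, never zeroed.
- Root-finding tolerances: 1e-10 on the blur calibration (τ on a log
  grid), 1e-12 on the proxy flip probability.
- Logistic fits error on single-class outcomes and on fitted
  probabilities at the 0/1 boundary (separation) rather than returning
  unstable estimates.
- Empty call tables, empty catalogs, zero-carrier regions and all-missing
  subjects each have defined behaviour (empty outputs, "absent" flags, NA
  scores) covered by tests.

## Problem sizes and runtime

The default study scale is n = 2348 subjects, 32 SNPs and 84 CNV regions;
one full pipeline run (`run_pipeline()`) takes a few seconds on one CPU.
The recovery study uses 50 replicate cohorts at full scale (about two
minutes); ROC coverage and calibration checks use a few hundred
replicates at reduced n chosen to keep Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

- The generator's Gaussian BMI lacks the right skew of real BMI, so the
  QC-truncation interaction described above is specific to simulation.
- Proxy markers model a single correlated stand-in per SNP, not LD
  structure; no haplotype-level scoring is possible.
- Catalog detectability (which literature CNVs an array can see at all)
  depends on probe content and is outside what this artifact can test.
- No mixed-model heritability estimation, genome-wide scans, liftover, or
  CNV calling from intensities: those stages produce the inputs this
  package consumes or simulates.
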