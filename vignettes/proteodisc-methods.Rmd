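---
title: "Methods: missingness-aware sparse PLS-DA analysis of DIA proteomes"
author: "proteodisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: missingness-aware sparse PLS-DA analysis of DIA proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodisc)
```

# Scope and model

proteodisc analyses wide protein-group intensity matrices from label-free
data-independent-acquisition (DIA) mass spectrometry of clinical cohorts —
the motivating application is muscle-biopsy proteomes of idiopathic
inflammatory myopathies (IBM, PM-Mito, ASyS, DM, IMNM, against non-diseased
controls), but nothing in the machinery is tissue-specific. The pipeline has
five statistical layers:

1. **Missingness-stratified imputation.** DIA intensities are missing
   predominantly because low-abundance ions fall below the detection limit
   (missing not at random, left-censored), with a smaller completely-random
   component. Proteins missing in more than 70% of the cohort's samples are
   removed outright. Surviving proteins with *low* missingness (fraction
   strictly below 0.20) are treated as missing-at-random-like and imputed by
   K-nearest-neighbour averaging; proteins with *moderate* missingness
   (0.20 up to and including 0.70) are treated as censored and imputed by
   downshifted normal sampling on the log2 scale. Zero-variance proteins are
   then excluded because they carry no information and break unit-variance
   scaling.
2. **Sparse PLS-DA.** Class labels are one-hot encoded into a dummy matrix
   $Y$; latent components $t_h = X a_h$ maximize covariance with $Y$ under a
   cardinality constraint: at most $\mathrm{keepX}_h$ proteins carry nonzero
   weight in $a_h$. The constraint is enforced inside NIPALS by
   soft-thresholding the loading update at the
   $(\mathrm{keepX}_h + 1)$-largest absolute entry — the Lasso-style
   operator parameterized by a count rather than a penalty $\lambda$, which
   is what gets tuned in practice.
3. **Model selection.** $\mathrm{keepX}$ and the number of components are
   tuned by repeated stratified M-fold cross-validation (default 5-fold,
   10 repeats) on the balanced error rate (BER), the mean of per-class
   misclassification rates, which is insensitive to the strong class
   imbalance of clinical cohorts. Per-class discrimination is reported as
   one-vs-rest AUROC of the dummy-regression decision scores, mean ± SD
   across repeats.
4. **Per-protein statistics.** Group means, log2 fold changes, one-way
   ANOVA (or pooled-variance Student t for two-sided contrasts), and
   Benjamini–Hochberg q-values with significance at $q \le 0.05$. Proteins
   rank by ascending q, then descending |fold change|, then identifier.
5. **Ranked-list GSEA and dual-contrast quadrants.** The weighted
   Kolmogorov–Smirnov running sum over the ranked list gives an enrichment
   score per gene set; a gene-permutation null (random same-size sets)
   yields permutation p-values and normalized enrichment scores. The
   quadrant analysis cross-tabulates two fold-change axes that share a
   reference group, separating shared from disease-specific changes.

# Tunable parameters

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| `drop_threshold` | 0.70 | missing fraction | proteins absent from most samples cannot be imputed credibly; fraction exactly 0.70 is retained (removal is strictly `>`) |
| `low_threshold` | 0.20 | missing fraction | boundary between KNN (sporadic missingness) and censoring-style imputation; 0.20 itself routes to the censored stratum |
| `k` | 10 | neighbour proteins | conventional neighbourhood size; distances are Euclidean over co-observed samples, normalized by co-observation count |
| `shift` (d) | 1.8 | per-sample SD | centre of the imputation distribution sits 1.8 SDs below the sample mean — the conventional default of downshift imputation |
| `width` (w) | 0.3 | per-sample SD | imputation spread; narrow so imputed values stay in the censored tail |
| `keepX` grid | 5–50 | proteins/component | tuned by CV; the grid should bracket the expected signature size |
| `folds`, `repeats` | 5, 10 | — | repeated stratified CV; repeats give the ± SD reporting |
| `distance` | `max_dist` | — | class = largest back-transformed dummy prediction; `centroid_dist` and `mahalanobis_dist` available |
| GSEA `exponent` | 1 | — | weighted KS statistic; 0 gives the unweighted classic |
| GSEA `nperm` | 1000 | permutations | resolution of the permutation p-value (smallest attainable p = 1/(nperm+1)) |
| `min_size`/`max_size` | 10 / 500 | set size | standard preranked bounds after intersecting with the list |

Imputation operates on the log2 scale throughout: downshifted-normal
sampling is defined there (log-normal raw intensities), and KNN distances on
log2 values are not dominated by a few high-abundance proteins.

# The synthetic cohort generator

Validation is recovery-based: `generate_cohort()` plants known structure
and the tests check the pipeline finds exactly that. The generator draws
log2 abundance

$$x_{ps} = \mu_0 + \beta_p + \Delta_{p,g(s)} + \varepsilon_{ps},\qquad
\beta_p \sim N(0, \sigma_0^2),\ \varepsilon_{ps} \sim N(0, \sigma_e^2),$$

exponentiates to the raw scale, and drops each cell with probability
$\mathrm{mcar} + (1-\mathrm{mcar}) \cdot \mathrm{logistic}((m - x)/s)$ — the
simplest mechanism producing the left-censoring that downshift imputation
presumes. Defaults: $\mu_0 = 20$, $\sigma_0 = 1.8$ (between-protein spread
of DIA protein-group quantities), $\sigma_e = 0.5$ (roughly a 40%
within-group biological CV), effect size 2 log2 units on planted proteins,
$m = \mu_0 - 1.5\sigma_0$, $s = 1$, $\mathrm{mcar} = 0.02$. The MNAR
midpoint and scale were calibrated once, by simulation, so that a realistic
20–40% of proteins land in the moderate-missingness stratum (observed:
about 24% at the defaults, overall missingness about 16%); they were fixed
before any acceptance measurement and are not revisited.

Cohort presets mirror the two myositis cohort designs the pipeline targets:
`cross_sectional` (ASyS 5, DM 3, IMNM 5, IBM 18) and `longitudinal`
(NDC 7, IBM 10, PM-Mito 14); `benchmark` is a balanced 3 × 20 design with
10 planted proteins used for recovery experiments. Each planted protein is
shifted in exactly one non-reference group, cycling through the affected
groups, so multi-class discrimination genuinely requires more than one
latent component.

What the generator does **not** emulate: peptide-level structure and shared
peptides, batch/run-order effects, correlated protein modules, heavy-tailed
or skewed residuals, and sample-specific normalization artefacts. Passing
recovery tests therefore demonstrates the machinery is correct under the
model's own assumptions, not that real cohorts will separate this cleanly —
on real data the reported CV metrics, not the synthetic benchmarks, are the
evidence.

# Numerical choices

- **NIPALS convergence.** The loading update iterates to `tol = 1e-9`
  (change in $a_h$, sign-invariant) with a cap of 5000 iterations. The
  tight tolerance keeps the dense-limit fit within $10^{-6}$ of the
  closed-form per-component SVD solution; convergence is linear and can be
  slow on weak-signal folds. The sparse update can also enter a period-2
  limit cycle (two supports with near-equal objective on signal-free
  data); the iteration detects the cycle and accepts the current iterate.
- **Sign convention.** The largest-|loading| entry of each component is
  made positive, so fits are deterministic and comparable across runs.
- **Threshold ties.** Soft-thresholding keeps the `keepX` largest absolute
  loadings with ties broken by column order (protein id order), so the
  selected support is deterministic; an exact tie at the threshold shrinks
  to zero, so the support can be smaller than `keepX`, never larger.
- **Degenerate tests.** A protein with zero between- and within-group
  variance reports $p = 1$ (no evidence); zero within-group variance with
  real group differences reports $p = 0$ (infinite F). Zero p-values are
  clamped to the smallest positive double before $-\log_{10}$ ranking.
- **Fold assignment.** Within each repeat, class members are shuffled and
  dealt to folds cyclically with a rotating offset, so every fold receives
  a class representative whenever the class has at least `folds` members,
  and small classes spread maximally.
- **Imputation RNG.** Downshift draws are consumed column by column
  (samples in order, proteins in row order) after seeding R's
  Mersenne-Twister with inversion normals, so imputed matrices are
  bit-reproducible; the seed is echoed in the preprocessing report.
- **Stage seeds.** The pipeline derives per-stage seeds from the global
  seed by fixed offsets (imputation +1, CV +2, tuning +3, GSEA +4), so
  adding a stage never perturbs the randomness of earlier stages.
- **GSEA p-values.** Sign-matched permutation tail with +1 smoothing;
  NES = ES divided by the mean |null ES| of matching sign; BH adjustment
  across retained sets. With no sign-matching null ES the p-value floors
  at 1/(nperm+1) and NES is reported missing.

# Design decisions on genuinely open points

- **Imputation inside or outside CV.** Imputation runs once on the full
  cohort, before cross-validation, matching the stated processing order of
  the motivating analyses. This is a mild leakage caveat (imputation
  parameters see all samples); the model-selection layer itself is strict —
  centring, scaling and the sparse support are recomputed from training
  folds only, which the tests assert by corrupting a test-only sample.
- **Per-cohort profiling.** Missing fractions are computed within the
  cohort being modelled, not across cohorts measured separately.
- **Differential route.** Both ANOVA + BH q-values (default) and Student's
  t + Bonferroni are implemented, since published analyses of this kind
  use either; density-based local-FDR estimation is deliberately out of
  scope. All significance thresholds are on the adjusted value at 0.05.
- **GSEA ranking metric.** `sign(FC) * (-log10 p)` by default — it encodes
  both direction and strength of evidence; raw log2 fold change is
  available. The optional pre-filter (restrict the list to adjusted — or
  raw — p below a threshold) is exposed because both conventions appear in
  practice.
- **Quadrant thresholds.** Fold-change threshold 1 on the log2 scale
  (2-fold) with significance required in both contrasts for "shared"
  calls; both are arguments, since the underlying scatter-plot analysis
  draws no canonical cutoff.
- **Clustered-image-map clustering.** Complete linkage on Euclidean
  distances, the common CIM default; configurable.
- **Components vs explained variance.** The number of components is a
  tuned quantity, not fixed at two or three; reported explained variance is
  per component against the centred/scaled X, so totals are bounded by 1.

# Problem sizes used in validation

The shipped validation suite exercises: a 60 × 200 dense-limit equivalence
check against a per-component SVD reference; the 3 × 20-sample, 500-protein
benchmark cohort with 10 planted proteins at a 2 log2-unit shift
(recovery, CV BER, one-vs-rest AUROC, and a permuted-label chance
control at 5-fold × 10 repeats); 10⁴-draw imputation contracts; 500-protein
null cohorts for ANOVA calibration; 200-item ranked lists with 1000
permutations for enrichment; and a full longitudinal-preset pipeline run
(tuning, CV, two contrasts, GSEA, quadrants) checked for byte-identical
reproducibility. These sizes were chosen as the smallest at which the
distributional claims are sharp.

# Known limitations

- No moderated (empirical-Bayes) variance shrinkage; with very few samples
  per group the per-protein tests are noisier than limma-style analysis.
- No covariate adjustment (age, sex are carried in metadata but unused).
- Gene-permutation (not phenotype-permutation) GSEA null: correlation
  between proteins is not preserved under the null, which can be
  anti-conservative for strongly co-expressed sets.
- Protein identifiers are taken verbatim; enrichment collections must use
  the same namespace (no identifier mapping).
- Cross-run normalization is assumed done upstream (as in DIA-NN's
  median-based normalization); the pipeline does not re-normalize.

# A minimal run

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_config(preset = "benchmark", seed = 1))
res <- run_pipeline(list(
  matrix = coh$matrix, metadata = coh$metadata, seed = 1,
  tuning = list(keepX_grid = c(5, 10, 15, 20), ncomp_max = 2)))
res
res$cv
summary(res$model)
```
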