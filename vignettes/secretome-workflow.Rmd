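---
title: "Paired secretome analysis and the tumorness signature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired secretome analysis and the tumorness signature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretoscope)
```

## The data and the problem

Tissue explants cultured for 24 h release soluble molecules — cytokines,
chemokines, growth factors, metalloproteinases, adipokines — into the
supernatant; multiplex immunoassays (Luminex, MSD) quantify dozens of these
analytes at once in pg/mL. When each cancer patient contributes a tumor
piece (`T`) and a macroscopically normal adjacent piece (`J`,
"juxta-tumor"), the pair forms its own matched control, and the analysis
question becomes: *which secreted molecules, and which combinations of
them, characterize the malignant tissue?*

Three features of such data drive the design of every stage here:

1. **Detection-limit censoring.** Each assay batch has a lower and an upper
   limit of detection per analyte. Out-of-range cells are *censored*, not
   missing at random — a below-LOD cell says "less than the limit".
2. **Log-normality.** Concentrations span orders of magnitude and are
   approximately log-normal; all analyses run on log10 concentrations
   (natural logs only for the multivariate patient distance).
3. **Pairing.** The two tissues of a patient share explant handling and
   patient-level biology, so tests are paired, train/test splits are made
   at the patient level, and cross-validation folds keep pairs together.

## Preprocessing rules

**LOD imputation.** For each analyte, every below-LOD cell receives one
common value: half the mean of the lower limits of the batches in which
that analyte had out-of-range samples. Above-LOD cells receive the maximum
of the analyte's upper limits over batches. Flags are preserved, so any
downstream analysis can distinguish imputed from measured cells. The rule
defining the batch set is ambiguous in one respect: "batches that included
out-of-range samples" could mean batches with below-range samples for that
analyte, or batches with out-of-range samples in either direction. Both
readings are implemented (`batch_rule = "below"` / `"any"`); the default is
`"below"`, since the value being imputed is a below-range surrogate and
tying it to above-range events would couple unrelated tails.

**Low-detection exclusion.** An analyte detected (in range) in strictly
fewer than 5% of juxta-tumor samples is excluded from every multiparametric
analysis *except* the secretome distance, which deliberately keeps the full
panel (a tumor secreting a normally-undetectable molecule is real signal
for a dissimilarity). The denominator counts non-missing J cells only:
bead-aggregation dropout is assay failure, not non-detection, and counting
it would conflate detectability with technical loss.

**Missingness.** Bead aggregation leaves sporadic truly-missing cells.
These stay `NA` through preprocessing; each multivariate stage handles them
explicitly (pairwise deletion for the distance, model-based completion for
PCA and clustering, chained-equation multiple imputation for the
classifier).

## Paired comparison and the secretome distance

The per-patient, per-analyte *tumor-specific value* is
`log10(T) - log10(J)`. Per analyte we report the median fold, a two-sided
paired Student's t test on logged concentrations, and star codes
(`NS` > 0.05, `*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001). Raw p-values are
reported, as is conventional for these per-analyte panels; multiplicity
correction can be applied downstream if a discovery claim depends on it.

The secretome-based distance of a patient is the Euclidean distance between
the tumor and juxta profiles on natural-log concentrations, over analytes
observed (or LOD-imputed) on both sides. Patients are grouped at the 0.15
and 0.85 quantiles of the distance distribution (type-7 linear
interpolation, the standard empirical-CDF definition; boundary membership
inclusive) into low / intermediate / high groups — by construction 15%,
70%, 15% of patients. Ratios whose J side is a LOD-imputed value are kept
but flagged: the TGF-β-style bimodality (a sizable fraction of juxta
samples secreting nothing detectable) only surfaces if such ratios are
retained.

## PCA and metamolecules

Missing cells are completed by regularized iterative PCA: initialize at
column means, then alternate a rank-`ncp` SVD reconstruction (singular
values shrunk by the mean residual eigenvalue, damping noise-driven
components) with refilling of the missing cells, until the imputed cells
change by less than 1e-6 RMS (cap 1000 iterations; rank 2 by default, since
two components carry the interpreted structure). Observed cells are never
altered.

PCA is computed by SVD on centered, unit-variance-scaled columns.
Correlation PCA is the defensible default when analytes span pg/mL to
ng/mL scales; a flag disables scaling. Analyte contributions per component
are squared loadings normalized to 100%. Group ellipses use the per-group
Gaussian (mean, covariance) with semi-axes scaled by
`sqrt(qchisq(0.95, 2))`.

Metamolecules summarize groups of analytes with a shared tumor-specific
behavior: analytes are clustered on their log10-ratio profiles across
patients (Euclidean distance, Ward criterion — `hclust` method `ward.D2`,
which implements Ward's minimum-variance method on Euclidean distances),
the tree is cut at `k = 5` (a config default, not a constant of nature),
and each patient's metamolecule value for a cluster is the mean of that
cluster's log10 ratios. Ratios are clustered unscaled: they are already
unitless log fold-changes, and rescaling would equate strongly- and
weakly-varying analytes. Cluster labels I, II, ... are assigned by
descending median metamolecule value, so labels are stable across seeds
and data sets rather than depending on dendrogram layout.

## The tumorness signature

The supervised procedure, end to end, with one master seed fixing every
random element (split, imputation streams, CV folds):

1. **Split.** Patients (not samples) are split 70/30; both tissues follow
   the patient. `n_test = floor(0.3 n)`, so 422 patients give 296/126.
2. **Filters (train side only).** Near-zero-variance variables are dropped
   (most-frequent/second-most-frequent ratio > 19 and distinct-value share
   < 10%). After imputation, highly correlated analytes (|r| > 0.8 on the
   average train correlation matrix across imputations) are removed by a
   deterministic greedy rule: repeatedly take the worst pair and drop the
   member with the larger mean absolute correlation, ties broken
   lexicographically.
3. **Multiple imputation (per side).** Chained equations, m = 30 copies,
   10 cycles each: continuous variables by predictive mean matching
   (Bayesian coefficient draw, donor pool of 5 nearest predicted means —
   imputations stay on the observed support), binary categoricals by
   logistic draws. Predictors per variable are screened at minimum absolute
   correlation 0.1 against the variable or its missingness indicator, with
   surgery type, age at diagnosis, molecular class, invaded-node count,
   vascular emboli and the tissue outcome always forced in. Train and test
   are imputed separately so no test information reaches the model.
4. **Elastic net.** Per imputation, a logistic elastic net over a lambda
   path; lambda by 10-fold cross-validated binomial deviance with
   pair-preserving folds, under the one-standard-error rule (the largest
   lambda within one SE of the CV optimum); CV AUC and accuracy are
   computed from the prevalidated fold predictions at that lambda. The
   deviance/one-SE combination matters more than it may look: on a
   no-signal data set the CV curve is flat, so a CV-optimal lambda (or a
   rank-based CV measure like AUC, whose standard errors are small and
   noisy) degenerates to a tiny penalty that keeps nearly every variable —
   and does so consistently across imputations, defeating stability
   selection — whereas deviance with the one-SE rule collapses to the
   empty model, which is the correct null behavior for a signature.
   Predictors
   are standardized internally and coefficients reported on both the
   standardized scale (comparable bar heights) and the raw log10 scale
   (the scoring scale). Alpha is selected across imputations on three
   criteria in order — mean CV AUC, mean CV accuracy, retained-variable
   count — with a 0.005 near-tie tolerance on the first two: both are
   noisy cross-validation estimates, and on a well-separated cohort
   letting either act as a hard criterion reduces the choice to CV noise
   (and systematically favors dense, ridge-like mixtures, since
   keeping many correlated analytes buys a fraction of a percent of CV
   accuracy). Within near-ties the deterministic criteria decide: fewer
   retained variables, then the sparser (larger) alpha. The grid is
   0.1–1.0 in steps of 0.1.
5. **Stability aggregation.** An analyte enters the signature if selected
   in strictly more than half of the m models; its pooled coefficient is
   the median over the models that selected it, the intercept the median
   over all models. Per-imputation models keep their own CV lambda (the
   selection was defined per imputed dataset; pooling lambdas would blur
   that definition).
6. **Cutoff.** Over midpoints of consecutive sorted train scores, the
   threshold minimizing the distance between the ROC point (FPR, TPR) and
   the perfect corner (0, 1); ties toward higher specificity. The corner is
   (0, 1): a "point (0.1)" formulation of this rule is read as a
   typographic rendering of that corner, the standard closest-to-corner
   criterion.
7. **Evaluation.** Train (control) and test. Test-sample scores are the
   average over the m test-side imputations — only originally-missing cells
   differ between copies, so this is a per-sample pooling of imputation
   uncertainty before thresholding. Metrics: confusion matrix, accuracy,
   sensitivity/specificity (tumor positive), trapezoidal AUC.
8. **Clinical association.** One-way ANOVA of tumor-sample signature
   scores across each categorical clinical feature, with a `.` trend code
   at p ≤ 0.1.

## The synthetic cohort

The generator produces the full data-generating process the pipeline is
designed for, with known ground truth: 422 patients, 55 named analytes in
four assay batches.

- Per analyte, juxta concentrations are log-normal (`mu_j`, `sigma` on the
  log10 scale, sd 0.45 for most analytes, 0.55 for the heterogeneous
  near-null cluster); tumor values add `delta * s_i` where `delta` is the
  analyte's planted log10 fold effect and `s_i` a latent per-patient tumor
  intensity (mean 1, sd 0.25, shifted additively by clinical covariates:
  pregnancy +0.08, grade I −0.15 / III +0.05, Ki-67 ≥ 20% +0.08,
  luminal-A −0.10; effects are cohort-centered so the mean score stays 1).
- Within-patient dependence is a shared Gaussian effect at correlation
  ρ = 0.5; each of the five fold clusters also shares a per-patient factor
  (sd 0.3) so analytes of a cluster co-vary as co-regulated molecules do —
  this factor, not the mean folds, is what makes the near-null clusters
  III and IV separable by Ward clustering. A small per-sample global
  secretion factor (sd 0.05) emulates explant mass/viability variation.
- Planted fold clusters: I (12 analytes, fold 4), II (9 analytes,
  metamolecule fold 14), III (14 analytes, 1.31), IV (9 analytes, 0.945),
  V (Leptin/CCL2/CCL3/CCL4/CCL8, 0.323), plus six analytes whose detection
  floor sits two sigma *above* their juxta mean, so they are detected in
  under 5% of juxta samples. The three TGF-β analytes are bimodal in
  juxta: 35% of patients secrete nothing detectable. Because those cells
  are censored and later imputed at half the mean lower limit, the
  bimodality alone contributes about fold 2.7 to cluster II's
  metamolecule; the TGF-β generative fold among secreting juxtas is
  therefore 5 (set by that closed-form compensation, not by iteration), so
  the cluster's observed median lands at the intended 14.
- Batch detection limits sit at `mu_j − 2.33 sigma` (about 1% censoring in
  juxta) with ±0.05 log10 batch-to-batch jitter, so the
  mean-of-lower-limits rule is exercised nontrivially; ceilings at about
  3 sigma above the tumor mean produce occasional above-LOD cells. Bead
  aggregation removes 2% of cells uniformly at random, disjoint from
  censoring.

Ground truth records each analyte's planted delta and cluster, the
config-defined discriminative set (|delta| ≥ 0.9 log10, i.e. the strongly
tumor-enriched cluster) and null set (|delta| ≤ 0.05), and each patient's
latent score. A null configuration (all deltas, bimodality and clinical
effects zero) supports type-I-error and chance-level-classifier
calibration.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real cohorts: analyte-specific assay noise and
plate-position effects; correlation between censoring and clinical
subgroups; non-log-normal heavy tails; informative (non-uniform)
missingness; the real panel's dense biological correlation structure, in
which co-secreted molecules correlate far more strongly than the planted
cluster factor. That last point matters for interpreting the signature
size: with the planted, nearly-orthogonal effects, ~26 analytes are
genuinely informative and the stability-aggregated elastic net correctly
retains most of them, whereas on a real cohort redundancy compresses the
retained set (the filter at |r| > 0.8 plus the L1 penalty share weight
among correlated analytes). For the same reason, checks that compare the
synthetic cohort against constants measured on a real cohort — the exact
size or membership of a published signature, or the share of variance on
the first principal component — are expected to disagree, and the suite
keeps them as documented failures rather than bending the generator
toward them: the generator's contract is the planted effect structure
(fold clusters, detection pattern, bimodality, pairing), not the real
data's covariance.

## Numerical choices and degenerate inputs

- Distance grouping with collapsed quantile cuts (all distances equal)
  assigns every patient to the intermediate group.
- A paired test with zero-variance nonzero differences reports a
  degenerate flag instead of a p-value; identical vectors give t = 0,
  p = 1.
- The ridge term 1e-5 stabilizes the PMM and logistic imputation draws
  when predictors are collinear.
- `choose_cutoff` on tied scores (fewer than two distinct values) is an
  error, not a silent cutoff.
- Iterative PCA imputation refuses columns with ≥ 50% missing cells and
  errors (carrying the last delta) rather than returning an unconverged
  completion.
- Seeds: one master seed is expanded into named substreams
  (`substream_seed`) for the generator, split, each imputation stream and
  the CV folds, so any stage can be rerun in isolation and reproduce the
  full-pipeline result exactly.

## Problem sizes used in the checks

The test suite runs the full study conditions once — 422 patients
(844 samples) × 55 analytes, m = 30 imputations, the 10-value alpha grid —
and shares that fit across checks; recovery and property checks that do
not need the full cohort run at 12–400 patients, and the null-cohort
classifier uses a single elastic-net mixing value since the null behavior
does not depend on alpha. The acceptance script reruns the full conditions
from scratch at the seed it is given.

## Known limitations

- The imputation model supports continuous and binary categorical targets;
  multi-level categoricals may serve as (complete) predictors but not as
  imputation targets.
- Coefficients are pooled by medians across imputations; no Rubin-style
  between-imputation variance is propagated, so the signature carries no
  standard errors (matching its use as a fixed classifier).
- The ROC-corner cutoff is chosen on pooled train scores, not per
  imputation; alternatives (per-imputation cutoffs, Youden's J) would give
  slightly different operating points.
- The benign-lesion application and ontology-based cluster annotation are
  out of scope; the cluster membership and score tables are the hand-off
  points.
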