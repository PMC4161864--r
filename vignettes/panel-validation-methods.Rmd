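---
title: "Validating a fixed blood miRNA panel against data-driven feature selection"
author: "mirUDB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a fixed blood miRNA panel against data-driven feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirUDB)
```

## The problem

Disease biomarkers selected from expression data are notoriously
unstable: rerun the selection on an independent cohort and a largely
different set of molecules comes out. A *universal disease biomarker*
(UDB) inverts the strategy: fix one small panel of blood miRNAs once
and ask how well the same panel separates patients from healthy
controls across many unrelated diseases, with no per-disease
reselection. `mirUDB` implements the full benchmarking pipeline for
this question: a fixed 12-miRNA panel (`udbPanel()`) versus features
chosen by PCA-based unsupervised feature extraction (FE) or by the
lasso, compared on discrimination accuracy under leave-one-out
cross-validation (LOOCV) and on the *stability* of the feature
selection itself.

The package operates on miRNA-by-sample expression matrices
(`MirnaExperiment`, an extension of `SummarizedExperiment`) with a
binary control/patient design, the format of public GEO blood miRNA
cohorts. Because such cohorts are a download away and heterogeneous, a
synthetic cohort generator with known ground truth
(`simulateCohort()`) stands in for them, so every stage of the
analysis is exercised, and its claims tested, at desk scale.

## The model and its components

### Per-sample normalization

Cohorts profiled by different platforms (microarray, qPCR, sequencing)
are made comparable by z-scoring every *sample*: each column of the
matrix is shifted and scaled to mean 0 and variance 1 across the
miRNAs it contains (`normalizeSamples()`). The variance uses the
$n-1$ divisor — the default of standard statistical environments; the
two conventions differ by a constant per cohort and cannot change any
classifier ranking. Whether normalization happens before or after the
feature-extraction step (or not at all, for some method/cohort
combinations) is a per-run configuration (`normalizationConfig()`),
defaulting to *before*. miRNAs with abnormally large values are removed
beforehand through an explicit per-cohort exclusion list
(`excludeFeatures()`, see `referenceExclusions()`); no automatic
outlier detector is applied, keeping the preprocessing auditable.

### The dual PCA embedding

With $X$ the $N \times M$ matrix of $N$ miRNAs by $M$ samples
($M < N$ in practice), PCA is computed by diagonalizing the sample-space
Gram matrix $X^\top X / N$ (`pcaDecompose()`), giving eigenvalues
$\lambda_k$ and orthonormal sample-space eigenvectors $u_k$. Both
embeddings derive from this single factorization:

* miRNA principal component scores $x_{ik} = (X u_k)_i$ — each miRNA as
  a point in component space;
* sample principal component scores $x_{kj} = \sqrt{\lambda_k}\,u_{kj}$
  — each sample as a point in the same number of dimensions.

Keeping all $M$ components reconstructs $X$ exactly, which the tests
assert, and the whole decomposition is label-free. Each eigenvector is
oriented so its largest-magnitude entry is positive; this removes the
sign indeterminacy of the eigenproblem from logs and tests and has no
statistical effect.

### Unsupervised outlier feature extraction

PCA-based unsupervised FE (`selectOutliers()`) keeps the miRNAs that
lie far from the origin in the first $K$ miRNA-score dimensions:
feature $i$ is selected when its Euclidean norm over those coordinates
strictly exceeds a threshold $\Delta$. $K = 2$ is the typical choice
and the default. Outlying miRNAs dominate the eigenvectors by
construction, so discarding the rest approximately preserves the
sample embedding that the classification uses — the rationale for
selecting features without ever looking at labels.

Two norm variants are exposed: the raw norm (default; $\Delta$ is then
on the scale of the data, as in published per-disease thresholds) and a
standardized norm in which each of the $K$ coordinates is first scaled
to unit variance across miRNAs, making $\Delta$ comparable across
cohorts. Because $\Delta$ is classically chosen by visual inspection,
`deltaForCount()` automates the choice reproducibly: the midpoint
between the `targetCount`-th and next largest norm (half the smallest
norm when all features are requested). A norm exactly equal to
$\Delta$ is *not* selected; consequently $\Delta$ at the maximum norm
selects nothing, and ties at the cut can make the realized count differ
from the target.

### Three discrimination schemes

* **PCA-based LDA** (`pcaLdaPredict()`): PCA is computed on *all*
  samples — the unlabeled test samples shape the projection, making the
  scheme semi-supervised — then a linear discriminant with equal class
  priors is fitted on the first $k$ sample PC scores of the training
  samples only. Equal priors mirror the class rebalancing used for the
  SVM. If the within-class scatter is singular (possible when $k$
  approaches the training size), a ridge of $10^{-8} \cdot
  \mathrm{tr}(S)/k$ is added and the event logged. The reported score
  is the patient-class posterior.
* **Gaussian-kernel SVM** (`svmPredict()`): radial kernel at the
  conventional defaults ($\gamma = 1/p$, cost 1), with class weights
  inversely proportional to training class frequencies so both groups
  carry equal total weight. The signed margin, oriented patient-positive,
  is the score.
* **Lasso-path discrimination** (`lassoPathPredict()`): a *numeric*
  lasso regression of the response 1 (control) / 2 (patient) — by
  design a regression, not a logistic model — fitted by least angle
  regression with the lasso modification (`larsPath()`, authored
  in-package and cross-checked against a coordinate-descent solver in
  the tests). Predictions are evaluated at a path fraction
  $s \in \{n/100\}$ of the final L1 norm; a held-out value strictly
  above 1.5 is called patient. The strict inequality matters only in
  the measure-zero boundary case — notably $s = 0$ with balanced
  classes, where every prediction is exactly 1.5 and the call is
  control. The features with nonzero coefficients at $s$ feed the
  stability bookkeeping.

### LOOCV and hyperparameter choice

All discrimination results use leave-one-out cross-validation
(`loocv()`): $M$ folds, each sample held out once. The optimal $k$
(number of PCs) or $s$ (path fraction) maximizes the LOOCV accuracy on
the same predictions that are reported, ties going to the smaller
value. There is no nested cross-validation — deliberately mirroring the
"optimal k / optimal s" reporting convention of the analyses this
package reproduces — so accuracies at the optimum carry the usual
selection optimism; treat them as comparative, not absolute.

`runDataset()` wires a cohort end to end under three feature modes:
the fixed panel (`subsetToPanel()`, members missing from a platform
are simply dropped and reported), PCA-FE (selection run *once* on all
samples, legitimate because it is label-free, and matching the
convention of reporting a single per-disease miRNA count), or the
lasso's own per-fold selection. For the stability statistic, FE is
instead re-run inside each fold (`loocvFeatureSelections()`), at a
fixed $\Delta$ by default (a fixed per-fold count is also available).

### The stability statistic

With $F_i$ the number of folds (out of $M$) in which miRNA $i$ was
selected and $\hat M$ the number of miRNAs ever selected, the
stability of a feature-extraction procedure is

$$S = \frac{\sum_{i:F_i>0} F_i}{M \hat M} \in [1/M,\, 1],$$

the mean selection frequency of ever-selected miRNAs. $S = 1$ exactly
when the selection never changes — a fixed panel is perfectly stable by
construction — and a single one-off selection attains the lower bound
$1/M$. The statistic is invariant to fold order and feature
relabeling, and strictly decreases when a stable feature loses one
occurrence.

### The significance screen

`perFeatureTests()` runs a two-sided Welch $t$-test per miRNA
(unequal variances — the safer default across heterogeneous cohorts and
the default of the environment this analysis family uses), adjusts by
the Benjamini–Hochberg step-up criterion (`bhAdjust()`) over all $N$
miRNAs, and flags adjusted $p < 0.05$. A miRNA with zero variance in
both groups is untestable: it receives $p = 1$ for equal means, $p = 0$
otherwise, and a `degenerate` flag. In these cohorts the number of
individually significant miRNAs is often tiny or zero, which is
precisely why per-miRNA significance filtering is not a workable
selection strategy and fixed panels or unsupervised FE are interesting
(`referenceSignificanceCounts()`).

### Evaluation

`summarizeEvaluation()` reports accuracy, sensitivity and specificity
(patient = positive class), the two-sided Fisher exact $p$ of the 2×2
confusion table (summing hypergeometric probabilities no larger than
the observed table's), the sample odds ratio — with a zero cell,
reported as infinite/zero alongside the Haldane–Anscombe $+0.5$
version, since the convention is otherwise underdetermined — and the
rank-statistic ROC AUC with half credit for ties, computed from the
classifier scores (LDA posterior, SVM margin, lasso predicted value).
Undefined metrics (empty class) are `NA`, never 0. Rendered tables
round to 3 decimals; all internal comparisons use full precision.

## The synthetic cohort generator

`simulateCohort()` draws
$$x_{ij} = b_i + \ell\, z_{B(i),j} + \delta_i\,[j \in \text{patients}]
 + \epsilon_{ij},$$
with per-feature baselines $b_i \sim N(0,1)$, blocks of
`correlationBlockSize` features sharing a standard-normal latent factor
$z$ with loading $\ell$, a mean shift $\delta$ (in noise-SD units) for
the informative features, and independent Gaussian noise. Defaults —
500 miRNAs, 20+20 samples, 10 informative features, blocks of 20 at
loading 0.7, 10 variance outliers at factor 25 — sit in the middle of
the cohort sizes this analysis targets (a few hundred miRNAs, tens of
samples).

Two design choices deserve justification:

* **Variance outliers are a co-varying family.** The inflated variance
  of the `nOutlierVariance` features is carried by one shared latent
  component with per-feature random sign and amplitude
  $\sqrt{f-1}\,\sigma$ (marginal variance still inflated exactly by the
  factor $f$). Ten *independent* high-variance features would span ten
  principal directions and no $K=2$ embedding could make them joint
  outliers; co-varying outlier families are also what real expression
  data produce (co-regulated, highly variable miRNA groups), and they
  are the structure outlier-based FE is designed to find.
* **Baseline spread equals the noise SD.** Per-sample z-scoring does
  not remove per-feature baselines, and features with extreme baselines
  are themselves PC-embedding outliers. Real runs of this analysis
  exclude abnormally-large miRNAs through the per-cohort config before
  anything else; the generator therefore emulates *post-exclusion*
  data, with baseline heterogeneity of the same order as the noise.

What the generator deliberately does **not** model: platform-specific
artifacts (qPCR Ct distributions, sequencing counts), batch structure,
non-Gaussian tails, and missingness other than entirely absent panel
members (`missingPanelIds`). Passing tests on this generator therefore
demonstrate the pipeline's correctness and its qualitative behaviour —
planted-signal recovery, stability ordering, null calibration — not
clinical performance on any real cohort.

Everything is deterministic given `seed` (the global RNG state is
saved and restored), and ground truth is returned beside the matrix so
recovery tests never infer it from identifiers.

## Numerical choices and degenerate inputs

* Labels are `control`/`patient` (0/1) everywhere except inside the
  lasso, which regresses on 1/2.
* Missing cells in an input table are an error with coordinates, never
  a silent `NA`; duplicate miRNA identifiers are an error by name.
* A constant sample cannot be z-scored and is refused by name.
* Excluding features down to fewer than 2 rows, or a panel with no
  member present, are errors rather than empty results.
* `larsPath` caps the active set at $\min(p, n-1)$, drops variables
  whose coefficient crosses zero (re-entering is allowed one step
  later), and treats near-zero-norm predictors as inert. Coefficients
  at a fraction $s$ interpolate linearly between path knots.
* All classifiers are deterministic given data and hyperparameters.

## Test design

The suite builds every fixture in code at small problem sizes chosen
for quick, well-powered checks: oracle comparisons (PCA vs SVD on 50
random matrices; the lasso path vs a coordinate-descent solver at
matched penalties and vs OLS at the path end; BH vs a brute-force
step-up oracle; Fisher exact vs full hypergeometric enumeration of all
2×2 tables with total at most 30; AUC vs explicit pair counting),
planted-structure recovery (10 co-varying variance outliers among 500
features; a 12-miRNA panel at effect size 3 with 25+25 samples), the
stability ordering across 5 seeds of the correlated-block design, and
a 20-seed null calibration at fixed hyperparameters ($k=2$, default
SVM, $s=0.5$). Fixed hyperparameters are used for the null because the
accuracy at a cross-validated optimum is upward-biased under the null
by the selection itself. The null check compares each method's mean
accuracy across seeds against the binomial 95% band of a single
LOOCV run and against three empirical standard errors: LOOCV fold
predictions within a run share training data and are positively
correlated, so a pooled binomial band would understate the real
variance.

## Known limitations

* The semi-supervised PCA step means test samples influence the
  projection (not the labels); accuracies are not estimates of
  performance on samples unseen at projection time.
* Optimal-$k$/-$s$ accuracies carry selection optimism (no nested CV),
  as discussed above.
* The stability comparison is between selection procedures at the
  configuration used here (fixed $\Delta$ per fold for FE, optimal $s$
  for the lasso); other configurations are supported but not the
  default.
* The Gaussian-after-normalization generator is the weakest assumption
  consistent with the use of $t$-tests and LDA, not a fitted model of
  any platform.
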