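---
title: "Multiple-kernel SVM fusion of clinical, EEG and PET features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-kernel SVM fusion of clinical, EEG and PET features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Internet gaming disorder (IGD) is commonly screened with self-administered
questionnaires, which are informative but subjective. Neuroimaging offers
objective complements — resting-state EEG spectral power and FDG-PET regional
glucose metabolism — but in small case-control cohorts almost no individual
EEG or PET feature separates patients from controls after multiple-testing
correction. Each imaging modality is weak on its own yet may still carry
complementary information. The question this package addresses is how to fuse
three such heterogeneous feature blocks into one classifier without diluting
the strong block (clinical scales) in a sea of weak features, and how to
quantify how much each modality contributes.

## The model

Let $x_i^{(m)}$ be the feature vector of subject $i$ in modality $m$
(clinical, EEG, PET) and $y_i \in \{+1, -1\}$ the group label (case /
control). Each modality induces a kernel matrix
$K^{(m)}_{ij} = k^{(m)}(x_i^{(m)}, x_j^{(m)})$. The fused kernel is the
convex combination

$$K(\beta) = \sum_m \beta_m K^{(m)}, \qquad \beta_m \ge 0,\ \sum_m \beta_m = 1 .$$

The simplex constraint makes the weights directly interpretable as modality
contributions. A standard soft-margin SVM is then trained on the combined
kernel by maximizing the dual

$$\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j y_i y_j
K_{ij}(\beta), \qquad \sum_i \alpha_i y_i = 0,\ 0 \le \alpha_i \le C,$$

with decision function $f(z) = \sum_i y_i \alpha_i k(x_i, z) + b$. `mksvm()`
solves this dual with an SMO-type maximal-violating-pair decomposition
(stopping when the KKT violation falls below $10^{-8}$); any solver meeting
that tolerance would be interchangeable. The bias $b$ is the mean of
$y_i - \sum_j \alpha_j y_j K_{ij}$ over free support vectors, falling back to
the midpoint of the feasible interval when every support vector sits on a
box bound. The box constraint is per-subject internally, which supports
weighted or duplicated observations.

## Kernels and leakage control

The kernel family is configurable (`kernel_spec()`): linear on z-scored
features (the default — the conventional choice when features far outnumber
subjects) or Gaussian RBF with a fixed or median-heuristic bandwidth. Two
design points matter more than the family:

* **Unit-diagonal (cosine) normalization** is applied to every per-modality
  kernel before combination. Without it, $\beta$ would conflate a modality's
  scale (its feature count and variance) with its information content, and
  "contribution" would be meaningless.
* **Training-only statistics.** Feature means/SDs and the median-heuristic
  bandwidth are always estimated from the training rows of the current fold
  and applied unchanged to held-out rows. `compute_kernel(X, spec,
  train_rows)` makes this explicit, and a metamorphic test verifies that
  deleting unrelated held-out rows changes nothing.

## Choosing the weights: nested cross-validation

With 52 subjects there is no room for a held-out tuning set, so the weight
search is nested: leave-one-out CV outside, and within each outer training
set a stratified 5-fold CV scores every candidate $\beta$ on a simplex grid
(step 0.05, 231 candidates for three modalities) by the pooled
inner-validation AUC. The maximizer is refit on the full outer training set
and scores the single held-out subject. Pooled held-out scores over all
outer folds give the reported ROC, AUC and confusion matrix; per-fold
selected weights are summarized as mean ± sample SD (`contribution_report()`).
Inner splits are stratified and seeded as `seed + outer_fold`, so the whole
procedure is reproducible from one master seed.

**Tie handling.** In small samples the pooled inner AUC saturates: with a
strong modality present, many grid points reach AUC 1 and are
indistinguishable by the inner criterion. Picking the first tying grid point
in enumeration order would systematically push weight toward whichever
modalities happen to come later in the lexicographic order — an artifact,
not evidence. The package instead takes the centroid of all tying grid
points (at the first cost value attaining the maximum) and snaps it to the
nearest grid point, breaking exact distance ties toward the first point.
This rule is symmetric across modalities, deterministic, and in simulation
recovers the signal-bearing modality where the first-point rule does not.

The cost parameter defaults to $C = 1$ with an optional inner-CV search over
a user-supplied set; with cosine-normalized kernels the fitted models are
insensitive to $C$ over an order of magnitude, and fixing it keeps the inner
loop honest about what is actually being tuned (the weights).

After the nested search, the fold-averaged weights are frozen and a plain
LOOCV (`loocv_fixed_weights()`) is run at that single $\beta$ — the same
two-stage protocol used to report the study's final confusion matrices.

## The synthetic cohort

No patient data ship with the package; `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes, so every stage
is testable end-to-end:

* **Clinical block.** Twelve scales drawn per group from independent
  Gaussians with the published group means and SDs (28 cases / 24 controls
  by default): strong separation on most scales (depression, impulsivity,
  stress, resilience, quality of life), none on age. Only total scores are
  generated, matching what is published. Age is generated but excluded from
  the classifier features (no group difference), as is the IGD severity
  score Y-IAT, which nearly defines the label (a flag re-includes it).
  Negative draws are truncated at zero by default because questionnaire
  totals are bounded below; truncation biases the realized means of
  low-mean/high-SD scales upward by several percent, so the generator
  calibration test runs with truncation disabled and the number of clipped
  draws is recorded in the dataset provenance.
* **EEG block.** 19 channels × 7 frequency bands × {absolute, relative}
  power = 266 standard-normal features. **PET block.** 90 ROI uptake
  values. Both carry a small group shift of $d = 0.1$ SD (5% of features at
  $d = 0.4$) and an exchangeable within-block correlation $\rho = 0.3$,
  emulating "few significant features after Bonferroni" while leaving a
  faint multivariate signal.

What the generator does **not** emulate: correlations *between* clinical
scales (they are drawn independently, because only marginal summaries are
published), spatial correlation structure over electrodes/ROIs beyond
exchangeability, non-Gaussian marginals of bounded scales, and any
subject-level coupling between modalities. One visible consequence: with
independent strong clinical scales the synthetic fusion problem is easier
than the real one (pooled LOOCV AUC near 1 rather than ≈ 0.88), so passing
tests demonstrate correctness of the machinery and qualitative orderings —
fusion ≥ stacking, weak modalities near chance — not the study's exact
operating point, which is unrecoverable without the original data.

## Evaluation and baselines

AUC is computed as the tie-aware Mann–Whitney concordance (checked in tests
against exhaustive pair enumeration and against pROC); ROC curves come from
score thresholds on the pooled LOOCV scores. Confusion metrics are reported
as percentages rounded to one decimal. The comparison harness runs the
conventional alternatives under the identical LOOCV protocol: a linear SVM,
random forest and gradient boosting on stacked features, an optional MLP
(one hidden layer of 32 units, weight decay and a capped iteration count
standing in for early stopping), and single-modality linear SVMs.

## Interpretation

`kernel_pca()` eigendecomposes the double-centered combined kernel; scores
are scaled eigenvectors, with each component's sign fixed so its
largest-magnitude score is positive (reproducible plots). A logistic model
on the first two components (`pc_separation()`) summarizes how much class
structure the fused kernel captures; under perfect separation, where the
logistic MLE diverges, the boundary is taken from the maximum-margin
direction instead and flagged. `kernel_heatmap()` renders each kernel with
subjects reordered so the case group leads, low similarity shown in red —
a well-fused kernel shows four distinct blocks.

## Numerical choices and degenerate inputs

* SMO stopping tolerance $10^{-8}$ on the KKT gap; support vectors are
  $\alpha_i > 10^{-8} C$, free ones additionally $\alpha_i < C(1 - 10^{-8})$.
* Kernels must be symmetric to $10^{-10}$ and PSD to
  $-10^{-8} \cdot \mathrm{tr}(K)/n$; violations are errors, not warnings.
* Zero-variance features are dropped with a warning before z-scoring;
  an all-constant block is an error.
* A kernel with a non-positive diagonal entry cannot be cosine-normalized
  and raises an error naming the subject.
* Decision scores of exactly zero classify as the positive class
  (documented tie rule).
* Single-class folds abort with an explicit error; stratified inner splits
  make this unreachable for the shipped cohort sizes.

## Problem sizes used in the shipped checks

The test suite exercises full-size cohorts (52 subjects, 366 features,
0.05 grid) for the weight-recovery and ordering simulations at 10 seeds
each, and reduced cohorts (12–16 subjects, coarse grids) everywhere the
property under test does not depend on scale. Generator calibration checks
use 10,000 subjects per group. These sizes are the package's own choice of
a demonstrative yet quick default; all are parameters, and nothing in the
implementation depends on them.

## Known limitations

* The weight grid is exhaustive rather than optimized; beyond ~4 modalities
  a gradient-based MKL formulation would be preferable.
* One kernel per modality; no learned or aligned kernels.
* No probability calibration on the SVM scores, and no permutation test on
  the cross-validated AUC.
* The fixed-weight LOOCV reuses the same subjects that produced the
  averaged weights; like the original two-stage protocol it mildly reuses
  information, which is why the nested result is the primary number.
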