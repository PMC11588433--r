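---
title: "Methods: from co-expression modules to the gene-immune portrait classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from co-expression modules to the gene-immune portrait classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqsig)
```

## What the package models

Advanced carotid atherosclerotic plaques differ from early lesions chiefly
in their inflammatory infiltrate — monocytic-lineage cells and neutrophils
accumulate as plaques progress — and in the transcriptional programs those
cells bring with them. `plaqsig` implements a diagnostic workflow built on
that biology: discover co-expressed gene modules, reduce the disease-
associated ("hub") modules to a sparse diagnostic signature, quantify immune
infiltration per sample, stratify advanced plaques into molecular subtypes,
and classify patients from a per-patient *gene-immune portrait* with a small
convolutional network. Everything is exercised on synthetic cohorts with
known ground truth, so each stage's claim is testable.

## The synthetic cohort generator

`generate_cohort()` builds a two-class (early / advanced) bulk-expression
cohort as a mixture of cell-population profiles:

1. **Population profiles.** Ten populations (the standard marker-based
   microenvironment set: T cells, CD8 T cells, cytotoxic lymphocytes, B
   lineage, NK cells, monocytic lineage, myeloid dendritic cells,
   neutrophils, endothelial cells, fibroblasts) share a per-gene baseline
   drawn uniformly on log2 \[3, 7\]; each population's markers (5 per
   population by default) are elevated by `marker_boost = 5` log2 units in
   its own profile only.
2. **Mixing.** Per-sample mixing proportions are Dirichlet draws
   (concentration 8 per population; the advanced class doubles the
   monocytic-lineage and neutrophil weight). In addition, each advanced
   sample draws an *infiltration multiplier* u ~ U(0.25, 4) applied to the
   monocytic and neutrophil concentrations. This multiplier is what couples
   the two inflammatory populations: plain Dirichlet draws make mixture
   components negatively correlated, whereas advanced plaques vary mainly in
   how much inflammatory infiltrate they carry overall, so monocyte and
   neutrophil abundance rise and fall together across patients. Without the
   shared gradient no subtype could be high in both — with it, the subtype
   contrast reproduces the expected direction.
3. **Composition.** Expression is mixed on the linear scale and transformed
   as `log2(sum_k p_k 2^profile_k + 1)` — bulk intensities add linearly, and
   the downstream deconvolution scores are tested on the scale they assume.
4. **Planted truth.** Eight signature genes (disjoint from all markers)
   receive a class shift (default +1.5 log2) in advanced samples; planted
   co-expression modules add `loading x latent factor` terms, where a
   module's latent factor is standard normal and can itself be shifted
   between classes (`class_delta`) to make the module disease-associated the
   way hub modules are; finally Gaussian noise (`noise_sd`, default 0.3
   log2) is added and expression floored at zero.

The generator returns the complete ground truth (labels, mixing proportions,
module membership, signature effects), which the tests use for recovery
checks. One master seed drives deterministic per-stage substreams, so a
cohort, its test-set sibling and every downstream stage are independently
reproducible.

**What the generator does not emulate:** single-cell counts and dropout,
batch effects, probe-level microarray artefacts, correlated marker noise,
and any real covariance between the signature genes and the immune mixture
beyond what the class labels induce. Green recovery tests therefore show
that the *methods* behave as claimed under their own assumptions — not that
the original cohorts would yield the same genes.

## Co-expression core

The network stage is a compact WGCNA-style core:

* **Soft threshold.** `soft_threshold_scan()` raises `|cor|` (or
  `((1+cor)/2)` when signed) to candidate powers and measures scale-free
  fit as the signed R² of `log10 p(k)` against `log10 k` over 10
  connectivity bins (R² times minus the sign of the slope). The chosen
  power is the smallest reaching 0.80, else the best-fitting power, flagged
  as a fallback. A known degeneracy documented here: on pure-noise data,
  high powers collapse connectivity into a heavy-tailed distribution that
  *looks* scale-free, so the fit statistic alone cannot certify real
  structure — module detection downstream (which finds nothing on noise) is
  the meaningful null control.
* **TOM.** `tom_similarity()` implements
  `TOM_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, unit
  diagonal; the test suite checks it against an O(n³) triple-loop oracle at
  1e-10.
* **Modules.** Average-linkage clustering on `1 - TOM` with a *static
  absolute* cut (default height 0.95) and a minimum module size of 10;
  clusters below the size floor are unassigned (label 0), modules are
  numbered by decreasing size. We chose an absolute cut (the
  `cutreeStatic` convention) over a cut relative to the merge range: a
  relative cut just below the dendrogram root always yields two or three
  large clusters, so independent genes would be labelled as modules; under
  an absolute cut, noise genes merge above the threshold and remain
  unassigned while planted modules merge far below it. Dynamic tree cutting
  and eigengene-based module merging are out of scope.
* **Eigengenes and kME.** A module eigengene is the unit-variance first
  principal component of the gene-standardised member submatrix, sign-fixed
  so its mean correlation with members is non-negative; kME is each gene's
  Pearson correlation with each eigengene. Hub genes are the top 25 members
  per hub module by kME (ties broken by gene id for determinism), so four
  disjoint hub modules give the 100-gene hub list used downstream.
* **Metacell smoothing.** `metacell_aggregate()` replaces each sample by
  the mean of itself and its k nearest neighbours in PC space — a
  deliberately simple stand-in for metacell construction; the downstream
  logic only needs a denoised matrix, and the step is off (`k = 0`) by
  default.

## Signature selection

`univariate_screen()` fits one logistic model per gene and keeps genes with
Wald p < 0.05; complete separation (common at large effect sizes) switches
that gene to a likelihood-ratio test and flags it. `lasso_select()` runs
L1-penalised logistic regression (via glmnet) with internally standardised
features and stratified 10-fold cross-validation on binomial deviance. The
penalty defaults to the deviance-minimising lambda (`lambda_rule = "min"`,
switchable to `"1se"`). On the study conditions (60 + 60 samples, +1.5 log2
effect, 0.3 noise) the screen-plus-LASSO pipeline recovers the planted
8-gene signature with a median of 8/8 and no false positives.

A limitation worth stating plainly: on pure-noise cohorts the two-stage
pipeline usually selects a *few* genes rather than none, whichever lambda
rule is used, because the screen forwards exactly those noise genes that
discriminate in-sample and cross-validated LASSO inherits that selection
bias. The suite asserts the realistic property (false selections stay
bounded), not a zero-selection guarantee.

## Immune and gene-set scoring

* `mcp_score()` — marker-mean abundance: the score of a population in a
  sample is the mean log2 expression of its markers, the transparent core
  of marker-based microenvironment scoring. On synthetic mixtures the
  scores track the planted proportions (Spearman > 0.9 per population at
  noise 0.3, n = 40).
* `ssgsea_score()` — a single-sample rank-based random walk: genes are
  ranked within each sample (average ranks on ties), in-set steps are
  weighted by rank^alpha (alpha = 0.25), out-of-set steps are uniform, and
  the score is the area between the two cumulative curves. We use this
  single, brute-force-checkable statistic for all single-sample enrichment
  (in place of a Gaussian-kernel CDF variant): it depends only on
  within-sample ranks, so any monotone per-sample transform leaves it
  unchanged, and the direction-of-difference claims it supports are
  preserved.
* `module_score()` — the bin-matched control score: genes are binned by
  average expression (24 bins), each set gene draws 100 controls from its
  bin, and the score is mean(set) − mean(controls); a seed makes the draw
  reproducible, and small bins fall back to sampling with replacement with
  a warning.
* `correlate_gene_immune()` — Spearman (default) or Pearson correlations of
  signature genes against population scores, with BH adjustment across the
  whole gene × population grid. Both correlation conventions appear in this
  literature; Spearman is the default as the rank-based, outlier-robust
  choice.

## NMF subtyping

`nmf_factorize()` minimises the Frobenius reconstruction error with
Lee-Seung multiplicative updates (epsilon 1e-12 in denominators), keeps the
best of 30 random restarts, and records the objective trace — monotone
non-increase is asserted per iteration in the tests, and exact rank-2
inputs are recovered to relative error below 1e-4. Matrices with negative
entries (e.g. normalised portraits) are shifted by their global minimum —
a global rather than per-gene shift preserves between-gene contrasts.
Samples are assigned to the dominant component of the column-normalised
coefficient matrix; rank is fixed at 2 to mirror the two-subtype structure,
with `cophenetic_rank_scan()` offered as a stability diagnostic rather than
an automatic selector. Subtype contrasts go through the normality-gated
two-group test with BH adjustment.

## Benchmarking and evaluation

`repeated_cv_benchmark()` runs stratified 5-fold cross-validation, ten
repetitions re-randomised per repetition, for random forest (500 trees,
sqrt(p) features per split), L1-penalised logistic regression, k-NN (k = 5,
features standardised inside the fold), naive Bayes and a linear SVM
(decision values as scores). Model implementations come from their standard
libraries — the benchmark models are commodity components — while the CV
protocol, AUC (Mann-Whitney pair counting), ROC construction (thresholds at
unique scores; trapezoid area equal to the rank AUC to 1e-12), Youden
threshold (ties resolved to the lower threshold) and DeLong confidence
intervals are implemented here and tested against enumeration oracles and
pROC. All preprocessing is fitted inside training folds only, and
`fit_final_and_test()` refuses overlapping train/test sample ids.

## The gene-immune portrait and its CNN

A patient's portrait is the 8 × 10 matrix of signature-gene expression
divided by population abundance scores, `P_ij = expr_i / max(score_j,
1e-6)`, rows in fixed gene order, columns in fixed population order. The
ratio encodes gene activity *relative to* the cellular context: a gene high
simply because monocytes are abundant is flattened, while disproportionate
expression stands out. Portraits are per-sample constructs; the optional
z-normalisation is fitted on training samples only and applied unchanged to
test samples.

The classifier is a small convolutional network implemented in this
package (an R front end over a compiled im2col forward/backward core):
conv(32 filters, 3×3)
→ ReLU → conv(16 filters, 2×2) → ReLU → max-pool(2×2, floor semantics; a
dimension shorter than the window pools as one region, so a 4×4 input is
the smallest accepted) → flatten (an 8×10 portrait flows 8×10 → 6×8 → 5×7
→ 2×3, flattening to 96) → dense(16, ReLU) → dense(1, sigmoid). Training is
full-batch Adam (learning rate 1e-3) on binary cross-entropy for exactly
500 epochs, with loss and accuracy traces recorded; filter counts, kernel
and pool sizes and the loss follow the published architecture, while the
activation, hidden width, learning rate and batch regime are unstated there
and set as the defaults above. Everything is deterministic given the
configuration seed, and the analytic gradients are verified against central
finite differences (parameters are jittered in that check because zero
biases put ReLU pre-activations exactly on the non-differentiable point).

On the standard fixture (60 + 60 training, 30 + 30 independent test
samples, +1.5 log2 signature, class-dependent mixing) the CNN reaches a
median held-out AUC above 0.9 over five seeds. A network trained on
permuted labels aligns with the dominant portrait axis with a random sign,
so its single-run held-out AUC is strongly bimodal; the null calibration
therefore averages 20 permutation runs, whose mean is compatible with 0.5.

## Pipeline plumbing

`run_pipeline()` chains the stages from a schema-validated configuration
(unknown keys are rejected), writing plain TSV/GMT/JSON artifacts plus a
JSON manifest per stage (parameters, seed, input/output checksums). A rerun
with the same configuration and seed is byte-identical; any stage can be
re-run from existing artifacts, and a missing upstream artifact is reported
by name. In the demo configuration the hub modules are chosen as the
detected modules whose eigengenes correlate most with the class labels, the
synthetic analogue of selecting the modules enriched in the
disease-associated monocytes.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale: oracle
equivalences on 5-40-unit instances; recovery on 120-sample, 300-gene
cohorts (10 seeds); module recovery on 60-gene, 50-sample fixtures; the
portrait CNN on the 60+60 / 30+30 fixture with 5 signal seeds and 20
label-permutation runs; calibration with 2,000 null simulations and 20
permuted benchmark runs. These sizes were chosen so the full suite runs on
a laptop in minutes while keeping every Monte-Carlo margin comfortably
wider than its sampling error.

## Known limitations

* The synthetic cohorts are mixtures with independent log-normal noise; no
  batch structure, no count noise, no real marker cross-reactivity.
* The scale-free fit statistic is degenerate on noise at high powers (see
  above); interpret the chosen power together with module detection.
* The screen + LASSO pipeline does not control family-wise false selection
  on null data (selection bias through the screen); treat selected genes as
  candidates, not discoveries.
* Static tree cut only; modules separated by less than the cut height merge.
* The CNN is full-batch and small; it is a faithful implementation of the
  published architecture at portrait scale, not a general-purpose deep
  learning engine.
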