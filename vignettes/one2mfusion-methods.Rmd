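---
title: "Gene-expression-to-image fusion classification: methods and design"
author: "one2mfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-expression-to-image fusion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Blood gene-expression cohorts for Alzheimer's disease typically carry tens
of thousands of probes for a few hundred subjects across three diagnostic
groups — Alzheimer's disease (AD), mild cognitive impairment (MCI) and
normal controls (NC). This high-dimension/low-sample regime is hostile to
deep networks on the raw tabular data. The One2MFusion approach creates a
*second modality from the same measurements*: each subject's selected gene
values are arranged into a small grayscale image whose layout is learned
from the class structure, so that a convolutional network can exploit
spatial neighbourhoods of similarly discriminative genes. A feed-forward
network (FNN) reads the expression vector, a convolutional network (CNN)
reads the gene image, and a late-fusion network concatenates their feature
vectors and classifies jointly.

The pipeline, per binary task (e.g. AD vs NC):

1. **Merge and normalise** the datasets: per dataset, each gene is z-scored
   (population standard deviation); the datasets are concatenated and each
   gene is min–max scaled to $[0,1]$ over the combined cohort.
2. **Select genes** with LASSO regression of the binary label on all genes.
3. **Map genes to 2D**: score each selected gene by the Fisher distance,
   bin the genes into $K$ equal-count categories, embed genes in the plane
   with linear discriminant analysis (genes as observations, categories as
   classes), tighten the cloud by rotating the minimum-area enclosing
   rectangle to the axes, and rasterise onto an $R\times C$ pixel grid.
4. **Render images**: a sample's pixel holds the mean expression of the
   genes assigned to that pixel; empty pixels are zero.
5. **Classify** with the FNN, the CNN, and their fusion, under stratified
   five-fold cross-validation in which *every* upstream artifact (selection,
   scores, categories, map) is refitted on the four training folds only.

## Model components

### Normalisation

Given datasets $d = 1,\dots,D$ with expression $x^{(d)}_{gs}$, the merged
value is

$$z^{(d)}_{gs} = \frac{x^{(d)}_{gs} - \mu^{(d)}_g}{\sigma^{(d)}_g}, \qquad
  \tilde x_{gs} = \frac{z_{gs} - \min_s z_{gs}}{\max_s z_{gs} - \min_s z_{gs}} \in [0, 1],$$

with population (1/n) standard deviations. Constant gene rows map to zero
in both steps, avoiding NaN propagation; such genes carry no class signal.
Min–max scaling over the *combined* cohort preserves residual dataset
differences as within-$[0,1]$ structure while removing per-dataset affine
offsets; re-applying it is the identity (tested).

### LASSO gene selection

The objective is pinned explicitly, since a penalty weight is meaningless
without its scaling convention:

$$\min_{\beta_0, \beta}\; \frac{1}{n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2
  + \lambda \lVert\beta\rVert_1 ,$$

with predictors entering on their $[0,1]$ scale (no re-standardisation).
The coordinate-descent fit is delegated to `glmnet`, whose objective
divides the residual sum of squares by $2n$, so `lassoSelect()` passes
$\lambda/2$ down; a short decreasing penalty path supplies warm starts.
Coefficients with magnitude above $10^{-12}$ count as selected. The default
$\lambda = 10^{-6}$ keeps several hundred genes on cohorts of this size.
Genes enter the model only below the bound
$\lambda_{max} = 2\max_g |\mathrm{cov}(x_g, y - \bar y)|$ (population
covariance); at or above it an explicit empty-selection error advises a
smaller $\lambda$. During cross-validation the selection is refitted per
fold; fitting it once on the full data would leak test information into
the model.

### Fisher scoring and categorisation

For gene $g$ with class means $\mu_{1g},\mu_{0g}$ and population variances
$\sigma^2_{1g},\sigma^2_{0g}$:

$$F_g = \frac{(\mu_{1g}-\mu_{0g})^2}{\sigma^2_{1g}+\sigma^2_{0g}+\varepsilon},
  \qquad \varepsilon = 10^{-12}.$$

Genes are ranked ascending by $F_g$ (ties broken by gene index) and cut
into $K = 15$ contiguous blocks whose sizes differ by at most one; when
$n \bmod K \neq 0$ the larger blocks take the lower category numbers, a
frozen deterministic choice. $K = 15$ follows the published tuning over
$\{7, 9, \dots, 17\}$.

### LDA gene embedding

Each *gene* is an observation whose feature vector is its expression across
the training samples and whose class is its Fisher category — the only
reading under which "mapping genes into 2D with LDA" is well-posed, and the
reason at least $K \ge 3$ categories are required for two discriminant
axes. With between- and within-category scatter $S_b, S_w$ the axes solve
$S_w^{-1} S_b\, a = \lambda a$; the implementation whitens $S_w$ spectrally
(dropping eigenvalues below $s\,\epsilon_{mach}\,\lambda_{max}$, i.e. a
pseudo-inverse when $S_w$ is singular — routine here, since the number of
genes usually exceeds the sample count) and eigendecomposes the symmetric
whitened $S_b$. Each axis's largest-magnitude loading is made positive, so
the embedding is sign-deterministic. The projections are translation
invariant (scatter matrices ignore a global feature offset).

### Minimum-area enclosing rectangle

The convex hull of the gene cloud is computed, and by the rotating-calipers
property the minimum-area enclosing rectangle has a side collinear with a
hull edge; only hull-edge angles (reduced modulo 90° into $(-45°, 45°]$)
are candidates. All points are rotated by the negative of the winning angle
so the rectangle is axis-aligned; area ties within a $10^{-9}$ relative
band resolve to the smallest $|angle|$. Collinear or coincident point sets
raise a degeneracy error.

### Rasterisation and rendering

Each rotated axis is min–max scaled to $[0, C-1]$ / $[0, R-1]$ and rounded
half-up (`floor(x + 0.5)`), a bit-reproducible convention; pixel indices
are 1-based `(row, col)` with row 1 at the top. Genes landing on one pixel
are averaged per sample at render time; unoccupied pixels are zero. The
default resolution is $50\times 50$ — large enough that a few hundred
selected genes mostly occupy distinct pixels while collisions (and hence
averaging) still occur. Lower resolutions force more averaging; occupied
pixel count is non-increasing as resolution falls (tested).

### The three networks

* **FNN**: dense 128–64–32–32, rectifier activations; the final 32-unit
  layer is the exported feature layer, fixing $t = 32$.
* **CNN**: six 3×3 same-padding convolutions in pairs of 32/32, 64/64,
  128/128 filters, each pair followed by 2×2 max pooling (odd trailing
  rows/cols dropped, so images must be at least 8×8); then two dense layers
  of width $t$.
* **Fusion**: the two $t$-vectors concatenated into $\mathbb{R}^{2t}$,
  then dense 32 – dropout 0.4 – dense 32 and a sigmoid head, trained
  end-to-end from random initialisation as a single joint optimisation
  (branch pre-training is deliberately not the default).

The last two dense layers of each branch carry L1 ($10^{-5}$) + L2
($10^{-4}$) kernel penalties and dropout 0.4. Kernel geometry (3×3,
stride 1, same padding; 2×2 max pooling) is frozen at the community
defaults. Training minimises binary cross-entropy with Adam at learning
rate $10^{-4}$, batch size 30, Glorot-uniform initialisation, inverted
dropout, and Adam $\epsilon = 10^{-7}$.

### Early stopping

The monitored quantity is the epoch-mean *training* loss including the
regularisation penalty (no validation split is used). The first 250 epochs
(`warmup`) are ignored; afterwards training halts once 10 consecutive
epochs (`patience`) fail to improve strictly on the best monitored loss,
and the best-loss weights are restored. The rule alone need not terminate,
so a hard `max_epochs` cap (2000) is added. `earlyStopEpochs()` exposes the
rule as a pure function over a loss sequence, which is how it is unit
tested.

### Evaluation

`makeFolds()` deals each class round-robin over folds visited in order of
current size, giving per-class and overall fold-size spreads of at most
one. Thresholded metrics (accuracy, precision, recall, F1) use cut-off 0.5
with the first-named task group as the positive class; zero-division cases
are defined as 0 with a warning. AUC is the normalised Mann–Whitney
statistic with midranks, which equals the trapezoidal area under the
threshold-sweep ROC (asserted to $10^{-9}$ in tests, and cross-checked
against pROC). `GeneMap` objects record the sample ids they were fitted on
(`fittedOn`), and `runCV()` refuses to proceed if that set intersects the
held-out fold.

## The synthetic cohort generator

`simConfig()`/`simulateCohort()` emulate the structure of a merged
multi-study cohort at desk scale: several datasets on one probe namespace,
Gaussian per-gene expression around baselines drawn from $U(4, 8)$ (a
typical log-intensity range), standard deviation `noise_sd` (default 1), a
planted subset of informative genes whose AD-group mean is shifted by
`effect_size` (default 1.0, i.e. one noise SD), and per-dataset affine
batch effects — scale from $U(0.75, 1.25)$, offset from $U(-0.5, 0.5)$ —
chosen as a moderate, realistic inter-study distortion that the per-dataset
z-scoring must (and does) remove. When MCI is simulated its shift is
`effect_size`/2, midway between NC and AD, so pairwise tasks have graded
difficulty mirroring MCI's intermediate clinical status. The default cohort
is 3 datasets × 50 samples per class, 1000 genes with 60 informative.

What the generator does **not** emulate: probe-level microarray noise
(cross-hybridisation, intensity-dependent variance), correlated gene
modules, platform-specific probe sets, or label noise. Passing tests on
this generator therefore demonstrate that the pipeline's machinery is
correct and leak-free and that fusion preserves the stronger branch's
signal — not that the published cohort-level accuracies transfer to any
particular real dataset.

## Scaled-down replication experiments

The acceptance suite replicates the qualitative fusion result on the
default synthetic cohort (two classes × 150 samples over three batches,
1000 genes, 60 informative at effect size 1.0), with training capped at 60
epochs after a 20-epoch warm-up and gene images at 12×12 — sizes chosen so
the full three-model, five-fold experiment (plus its label-permuted null)
runs on a single CPU core in minutes while still exercising every stage,
including pixel collisions and all three pooling stages. At these
conditions the fusion model's mean AUC matches or exceeds the best single
branch, and label permutation collapses every model to chance
(AUC ≈ 0.5). On such strongly separable synthetic data both branches can
saturate near AUC 1; the published pattern in which the image branch
clearly beats the expression branch is a property of real cohorts and is
not asserted on synthetic data.

## Numerical and engineering choices

* The network engine is a compact, fully deterministic CPU implementation:
  dense algebra in R on BLAS, convolution/pooling kernels in compiled code
  (single-precision GEMMs — convolution stacks are robust to float32 and it
  doubles single-core throughput). A fixed seed fixes initialisation,
  shuffling and dropout; two runs with one seed are bitwise identical, which
  the determinism tests assert at the level of serialized reports.
* Probe intersection orders probes lexicographically, so results are
  independent of input file order.
* Population (not sample) standard deviations are used in z-scoring and
  Fisher variances; documented constants, tested explicitly.
* `feature_dim` not below the input gene count is a warning, not an error:
  tiny toy inputs are legitimate in tests even though the feature layer
  then does not compress.
* Degenerate inputs fail loudly: empty probe intersections, single-class
  responses, all-collinear gene clouds, zero coordinate ranges, images
  smaller than 8×8.

## Known limitations

* GEO ingestion parses series-matrix files and label characteristics by
  regular expression; probe-to-symbol collapsing and platform-specific
  normalisation are out of scope.
* The LASSO path at very small penalties on $p \gg n$ data retains roughly
  as many genes as samples; the published per-task gene counts depend on
  cohort details the synthetic generator does not reproduce.
* Training-loss early stopping (no validation split) follows the published
  protocol but can overfit relative to a validated stop.
* The 50×50 default image and 3×3/2×2 kernel geometry are conventions, not
  tuned optima; resolution interacts with the selected gene count through
  the collision rate.
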