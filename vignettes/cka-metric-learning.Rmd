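---
title: "Supervised metric learning by centered kernel alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised metric learning by centered kernel alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckametric)
```

## The model

`ckametric` addresses a recurring situation in computer-aided diagnosis
from morphometric features: a sample-by-feature table whose columns mix
physical units (volumes in mm³, areas in mm², thicknesses in mm), whose
discriminative content lives in a low-dimensional subspace, and whose
classes (e.g. healthy control, mild cognitive impairment, Alzheimer's
disease) are ordered along a severity continuum with the middle class
overlapping both ends. Plain Euclidean distance in such a table is
dominated by the largest-scale columns, which are usually not the
informative ones.

The package learns a generalized Euclidean (Mahalanobis-type) metric
$d_W(x, x')^2 = (x - x')\,W W^\top (x - x')^\top$ induced by a projection
$W \in \mathbb{R}^{P \times d}$, chosen so that the Gaussian kernel

$$\kappa_X(x, x') = \exp\!\big(-d_W(x,x')^2 / 2\sigma^2\big)$$

is maximally *aligned* with the class structure. Alignment is measured by
the empirical centered kernel alignment between the $N \times N$ data
kernel $K_X$ and the class-indicator label kernel $K_L$
($[K_L]_{nn'} = 1$ iff samples share a class):

$$\hat\rho(\bar K_X, \bar K_L) =
  \frac{\langle \bar K_X, \bar K_L\rangle_F}
       {\sqrt{\langle \bar K_X, \bar K_X\rangle_F
              \langle \bar K_L, \bar K_L\rangle_F}} \in [0, 1],$$

where $\bar K = H K H$ with $H = I - \tfrac1N \mathbf{1}\mathbf{1}^\top$ is
the double-centered kernel (elementwise: subtract row and column means, add
the grand mean). $\hat\rho$ is a normalized Hilbert–Schmidt-style
dependence measure: 1 when the data kernel reproduces the class partition,
0 when the centered kernels are orthogonal. The fitted projection
minimizes the cost

$$J(W) = -\log\langle \bar K_X(W), \bar K_L\rangle_F
         + \tfrac12 \log\langle \bar K_X(W), \bar K_X(W)\rangle_F
         \;=\; -\log\hat\rho + \text{const},$$

the first term rewarding similarity to the label kernel, the second acting
as a norm regularizer on the data kernel. The additive constant
$\tfrac12\log\langle\bar K_L,\bar K_L\rangle_F$ does not depend on $W$ and
is dropped. The label kernel is the delta kernel by default; `cka()`
accepts any precomputed kernel for extensions.

## Gradient and optimizer

The gradient of $J$ with respect to $W$ is computed analytically by the
chain rule through the kernel. Writing $S = (\partial J/\partial K)
\odot K$ and $L_S = \mathrm{diag}(S\mathbf{1}) - S$ (a graph Laplacian),

$$\nabla_Y J = -\tfrac{2}{\sigma^2} L_S Y, \qquad
  \nabla_W J = X^\top \nabla_Y J,$$

with $Y = XW$; for saturated layers the elementwise derivative of the
activation is interposed. Both paths are permanently guarded by a
central-finite-difference test (relative error $< 10^{-4}$).

The default optimizer is full-batch gradient descent with an Armijo
backtracking line search: every accepted step decreases the cost, so the
recorded `fit_history` is non-increasing by construction and the final
alignment can never fall below its value at initialization. Minibatch
stochastic gradient is available through `fit_config(batch_size = ...)`
(cost then recorded full-batch once per epoch; monotonicity is not
guaranteed on that path). Iterations stop at `max_iters`, at a relative
cost change below `tolerance`, or when no descent step is found.

Three further numerical choices matter:

* **Initialization.** $W$ starts at the top-$d$ principal components of
  the *z-scored* training features, with each column's sign fixed so its
  largest-magnitude element is positive (deterministic up to data). The
  z-scoring is essential — the package's feature tables mix mm³/mm²/mm
  scales, and unstandardized PCA provably picks the noise blocks (this is
  exercised by the `"scale-confounded"` test family). Center and scale are
  stored in the model and re-applied by `metric_transform()`.
* **Bandwidth.** $\sigma$ is set to the median of the positive pairwise
  distances among the projected points (the classical median heuristic),
  once after initialization; `fit_config(retune_every = R)` re-tunes it
  every $R$ iterations, and `bandwidth_strategy = "maxvar"` instead
  maximizes the variance of the off-diagonal kernel entries over a log
  grid around the median. The bandwidth-selection procedure referenced in
  the neuroimaging literature for this purpose is not fully specified in
  accessible form; the median heuristic is this package's own documented
  stand-in, not a claim of equivalence.
* **Multi-start.** The objective is nonconvex. For the linear metric the
  PCA start is almost always adequate, but saturated layers (below) have
  genuinely distinct local optima: on XOR-structured data, descent from a
  PCA start can settle in a state where a class's two clusters remain
  separate ($\hat\rho \approx 0.47$) instead of merging
  ($\hat\rho \approx 0.83$). `fit_config(n_restarts = k)` therefore runs
  the optimizer from the PCA start plus $k-1$ seeded random starts and
  keeps the solution with the best alignment. The default ($1$) preserves
  the deterministic behaviour; the pretraining tests use 5.
* **Floor.** $\hat\rho$ is clipped below at $10^{-12}$ before the log so
  the cost stays finite in early iterations.

A numerically degenerate kernel (all entries $\approx 1$, i.e. a centered
kernel of negligible norm) raises an error suggesting bandwidth re-tuning
rather than silently returning a flat gradient.

The target dimension defaults to $d = \min(P,\, 3C,\, N-1)$: alignment
with a $C$-class delta kernel needs only low rank, but a few extra
dimensions ease the optimization; any $d$ up to $P$ can be configured. No
orthogonality constraint is imposed on $W$ — the learned span is generally
non-orthogonal.

## Layer-wise pretraining

The linear metric is the single-layer, linear-activation special case of a
feed-forward stack $h^m = \vartheta(b^m + h^{m-1} W^m)$ with
$\vartheta(z) = (\tanh z + 1)/2 \in (0,1)$ and a softmax output layer.
`pretrain_network()` fits the hidden layers sequentially: layer $m$'s
weights maximize the alignment between the Gaussian kernel among its
saturated representations and the label kernel, holding earlier layers
fixed (they are never revisited) and keeping offsets $b^m$ at zero; only
fine-tuning (`nn_finetune()`, backpropagation on cross-entropy with
momentum) trains the offsets and the output layer. Each layer's
projection is initialized from the principal components of the previous
layer's output (padded with small random columns when the requested width
exceeds the input rank), and its bandwidth is tuned on that layer's own
scale — saturated coordinates lie in $(0,1)$, so pairwise distances are
bounded by $\sqrt{Q_m}$.

One structural property is worth knowing: with offsets pinned at zero, a
*single* saturating layer cannot collapse a class whose two centers are
mirror images through the origin ($\vartheta$ is strictly monotone, so
$\vartheta(a) = \vartheta(-a)$ only at $a = 0$). The XOR family is
therefore separable by the two-hidden-layer pipeline but not by the
one-hidden-layer one — the second layer operates on the $(0,1)$-offset
representation, where the zero-offset restriction no longer binds. The
pretraining tests use two hidden layers accordingly.

When alignment-based pretraining succeeds, fine-tuning starts from
representations that already cluster by class: on the XOR family the
pretrained network reaches a cross-entropy of 0.35 (half the two-class
chance loss $\log 2$) in a median of ~9 epochs versus ~80 from a random
initialization of the same architecture.

## Classifiers and the evaluation protocol

* `knn_classify()` votes among the $k$ nearest training points in the
  (optionally projected) space; vote ties break by smallest summed
  neighbour distance, then smallest class index — deterministic, unlike
  randomized tie-breaking. The paper-style grid is $k \in \{1,3,5,7,9\}$.
* `svm_classify()` trains a soft-margin SVM on the Gaussian kernel of the
  projected features via kernlab's SMO-type solver, one-vs-one for
  multi-class, grid $C \in \{0.1, 1, 10, 100, 1000\}$; a precomputed-kernel
  route exists and is tested to give identical predictions.
* `nn_finetune()` trains the full stack by gradient descent with momentum
  on cross-entropy; softmax rows sum to one by construction, and a
  non-finite loss aborts with a diagnostic rather than returning garbage.

`grid_search()` scores each grid point by subject-grouped $k$-fold
cross-validated accuracy (all scans of a subject share a fold; a subject
spanning folds is a hard error), breaking ties toward the simpler model.
`run_pipeline()` composes the full protocol: subject-grouped 70/30 split,
grid search on the training side, final fit, and test-set evaluation for
baseline and CKA-enhanced variants. CV accuracy is scored per-sample
within subject-grouped folds.

`score()` returns the overall accuracy $a = (\sum_c t_c)/N$ and per-class
true-positive fractions $\tau_c = t_c/N_c$; the identity
$a = \sum_c (N_c/N)\,\tau_c$ is asserted on random confusions in the
tests, pinning the accuracy definition. `std_tau` (the standard deviation
of the $\tau_c$, in percent) summarizes class balance. `bootstrap_ci()`
resamples test indices with replacement ($B = 1000$ by default),
reporting the replicate mean and percentile 2.5/97.5 interval; a resample
missing a class required by the measure is redrawn and counted.
`compare_significance()` is a one-sided Welch $t$-test in the direction
"enhanced exceeds baseline" at the 1% level. `per_class_auc()` computes
one-vs-rest rank-based AUCs (mid-rank ties) with the direction fixed so
label-independent scores give $\approx 0.5$ rather than an inflated value.

## The synthetic generator

No clinical dataset ships with the package (the motivating cohorts
require registered access), so `synth_spec()`/`synth_generate()` produce
tables with the statistical structure the method assumes, and every claim
in the test suite is exercised against them:

* a low-dimensional signal subspace with class-conditional Gaussian means
  (shared covariance), the middle class interpolated between the extremes
  by `intermediate_mix` (0.5 by default — the mild-cognitive-impairment
  analogue);
* nuisance dimensions in blocks whose scales mimic cortical volumes
  (~10³), subcortical volumes, surface areas, mean thickness (~2.5) and
  thickness dispersion (~0.5), so that unstandardized variance-based
  methods demonstrably fail;
* repeated scans per subject: subject-level means are drawn around the
  class mean (s.d. 1) and scans around the subject mean (s.d. 0.5), in
  the signal *and* nuisance dimensions, making within-subject correlation
  exceed between-subject correlation — which is what makes
  subject-grouped validation a real constraint;
* default class-size ratios 23:38:29 subjects, preserving a typical
  HC:MCI:AD cohort imbalance at a tenth of the scale, with 2–5 scans per
  subject (exact per-class scan totals can be pinned, which the
  cohort-scale test uses to hit $N = 3304$, $P = 310$ exactly);
* optional `"xor"` and `"annulus"` nonlinear families (two classes) for
  the pretraining tests.

The named fixtures are `tiny3class` (30 × 6 smoke instance),
`xor2class` (80 × 4, balanced XOR quadrants — not linearly separable) and
`scale-confounded` (60 × 10, one discriminative feature with essentially
disjoint class supports plus nine large-scale nuisance features; effect
size 6 total-s.d. units, because this family probes scale confounding,
not class overlap).

What passing tests on these families does **not** show: real morphometric
data have correlated features within anatomical regions, non-Gaussian
class-conditional distributions, site and scanner effects, and label
noise from uncertain clinical diagnoses. The generator emulates none of
these, so synthetic performance numbers (e.g. the near-perfect
scale-confounded accuracies) characterize the machinery, not expected
clinical performance.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at deliberately modest
sizes: 20 replicate cohorts of 60 samples for the metric/classifier
comparisons, 20 cohorts of 80 samples for pretraining, gradient checks at
$N = 10$, $P = 6$, and one cohort-scale pipeline run at $N = 3304$,
$P = 310$ (the full three-class shape with 896 subjects) with the k-nn
classifier, which completes in a few minutes on a single CPU. Every
random draw is seeded; fits are bitwise reproducible for a fixed seed on
one platform.

## Limitations

* The alignment objective is nonconvex; multi-start mitigates but does not
  eliminate local optima, and the reported `converged` flag refers to the
  chosen start only.
* Bandwidth selection is heuristic; a poorly scaled $\sigma$ flattens the
  kernel and the fit degenerates (detected and reported, not repaired).
* Only the empirical alignment estimator is computed; population-level
  alignment is out of scope, as are multiple-kernel variants, local
  metrics, second-order optimizers and end-to-end CKA training of the
  network.
* The delta label kernel treats all class confusions as equally costly;
  ordinal structure (control → mild impairment → disease) is not encoded.
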