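# ckametric

Supervised metric learning by **centered kernel alignment (CKA)** for
multi-class diagnostic classification, in R.

## The problem

Morphometric feature tables — e.g. region-wise cortical volumes (mm³),
surface areas (mm²) and thicknesses (mm) extracted from structural MRI —
mix measurement units and bury the few discriminative directions among
hundreds of nuisance dimensions. Distance-based classifiers (k-nn, Gaussian
kernel SVM) then spend their metric on whatever has the largest variance,
not on what separates healthy controls, mild cognitive impairment and
Alzheimer's disease. `ckametric` learns the metric instead: a linear
projection `W` such that distances measured as

```
d_W(x, x')² = (x − x') W Wᵀ (x − x')ᵀ
```

make a Gaussian kernel on the data resemble the class-label kernel as much
as possible.

## The statistic and the objective

For kernel matrices `K_X` and `K_L` on the same `N` samples, with
`K̄ = H K H`, `H = I − 11ᵀ/N` (double centering), the empirical centered
kernel alignment is

```
ρ̂(K̄_X, K̄_L) = ⟨K̄_X, K̄_L⟩_F / √(⟨K̄_X, K̄_X⟩_F ⟨K̄_L, K̄_L⟩_F)  ∈ [0, 1].
```

`K_X` is the Gaussian kernel `exp(−d_W(x, x')²/2σ²)` on the projected
features; `K_L` is the class-indicator (delta) kernel. The projection is
fitted by minimizing `−log ρ̂` with an analytic gradient (finite-difference
guarded in the tests), starting from the principal components of the
z-scored features, with the bandwidth `σ` set by the median heuristic on
projected pairwise distances. The same objective pretrains each hidden
layer of a feed-forward network, `h^m = ϑ(h^{m−1} W^m)` with
`ϑ(z) = (tanh z + 1)/2`, layer by layer against the label kernel — giving
discriminative initial weights for softmax/cross-entropy fine-tuning.

Downstream classifiers consume the learned space: k-nn (deterministic
tie-breaks), Gaussian-kernel SVM (kernlab's SMO solver, one-vs-one),
and the fine-tuned network. Evaluation follows the clinical-reporting
conventions: accuracy, per-class true-positive fractions τ_c (= sensitivity
/ specificity in two-class tasks), their balance `std_τ`, percentile
bootstrap 95% CIs from 1,000 test-set resamples, one-vs-rest per-class
AUCs, and a one-sided Welch t-test (1% level) comparing a classifier with
its CKA-enhanced version. Cross-validation and train/test splits are
*subject-grouped* throughout, so repeated scans of one subject never leak
across folds.

## Worked example

The `"scale-confounded"` synthetic family has two classes separated only
along feature 1, drowned by nine nuisance features on volume/area-like
scales, with two scans per subject:

```r
library(ckametric)
d <- make_fixture("scale-confounded")
test <- subject_split(d$subjects, d$labels, test_frac = 0.3, seed = 1)
model <- fit_metric(d$features[!test, ], d$labels[!test],
                    fit_config(max_iters = 400, tolerance = 1e-9, seed = 1))
model
#> CKA metric: P = 10 -> d = 6, sigma = 3.897, final rho = 0.9815 (converged)
round(sqrt(rowSums(model$W^2)), 3)
#>    signal_1    volume_1    volume_2    volume_3      area_1      area_2
#>       4.401       0.329       0.361       0.173       0.217       0.232
#>      area_3 thickness_1 thickness_2 thickness_3
#>       0.522       0.325       0.140       0.084
```

The fitted projection's row norms show the metric recovering the single
discriminative feature (4.40) and suppressing every nuisance row (≤ 0.52).
That translates directly into classification:

```r
pred0 <- knn_classify(d$features[!test, ], d$labels[!test],
                      d$features[test, ], k = 5)                 # raw metric
pred1 <- knn_classify(d$features[!test, ], d$labels[!test],
                      d$features[test, ], k = 5, model = model)  # learned metric
mean(pred0 == d$labels[test])  #> 0.25
mean(pred1 == d$labels[test])  #> 1
evaluate_predictions(d$labels[test], pred1, B = 1000, seed = 1)
#> accuracy 100.0% (95% CI 100.0-100.0), std_tau 0.0%
#>   tau_class1 100.0% (100.0-100.0)
#>   tau_class2 100.0% (100.0-100.0)
```

Raw Euclidean 5-nn lands at 25% (the large-scale noise dimensions carry
the within-subject correlation, so neighbours are scan repeats of the
wrong subjects); the learned metric reaches 100% on the held-out subjects.

`run_pipeline()` wires the whole protocol — subject-grouped 70/30 split,
grid search by grouped cross-validation, bootstrap evaluation — for
baseline and CKA variants of each classifier, and
`inst/cli/ckametric-cli.R` exposes `simulate`, `fit-metric`, `pretrain`,
`classify`, `evaluate` and `run` subcommands for shell use.

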