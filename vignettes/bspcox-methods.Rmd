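---
title: "Methods: blockwise sparse components for multi-omics survival models"
author: "bspcox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blockwise sparse components for multi-omics survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A multi-omics survival study supplies J omics layers — each an n × p_j
matrix of quantitative measurements on the same patients — and a
right-censored outcome (time, event). With p_j far larger than n, a Cox
model on raw variables is neither fittable nor interpretable. `bspcox`
reduces each layer to a handful of *block components* before any
survival modelling, in two stages.

### Stage 1: homogeneous blocks and one sparse component each

Variables are standardized (mean 0, variance 1, divisor n−1) and
clustered by the homogeneity criterion: a cluster C of standardized
variables has homogeneity H(C) = λ₁(C), the largest eigenvalue of its
correlation matrix, which equals the summed squared correlations of the
member variables with the cluster's synthetic variable (its first
principal component). Agglomeration starts from singletons — each with
homogeneity exactly 1 under the n−1 divisor — and greedily merges the
pair with the smallest homogeneity loss d(A,B) = λ₁(A) + λ₁(B) −
λ₁(A∪B). Because λ₁ is a maximum of a sum of squared correlations,
λ₁(A∪B) ≤ λ₁(A) + λ₁(B), so every merge height is nonnegative; heights
are not guaranteed monotone across merges (as with centroid linkage),
which is why the tree cut undoes merges by count rather than by
thresholding heights.

Each block then gets one sparse first principal component: the
elastic-net reconstruction problem

$$\min_{\alpha,\beta} \sum_i \lVert x_i - \alpha\beta'x_i\rVert^2 +
\lambda\lVert\beta\rVert^2, \qquad \lVert\alpha\rVert = 1,$$

with sparsity expressed directly as a nonzero-count budget
k = max(1, round(0.10·p_block)) using round-half-to-even. The component
score is Xβ̂/‖β̂‖, and the sign is fixed so the largest-magnitude
loading is positive.

The model this premises is blockwise-latent-factor structure: variables
within a block are noisy copies of one factor, blocks are near
independent, and a block's factor is what matters for outcome. The
synthetic generator (below) draws data from exactly this model.

### Stage 2: integration, Cox regression, evaluation

Component scores from all layers are column-bound ("parallel"
integration — every layer treated equally) without re-standardization,
so Cox coefficients stay on the component-score scale. The Cox model is
pruned by bidirectional stepwise AIC, and the resulting risk score
η = Σ b_k·sPC_k is evaluated by a cumulative/dynamic time-dependent ROC
at horizon t (cases: event by t; controls: event-free past t) and by
Harrell's concordance index. The selected model is drawn as a two-level
polar chart: sector radius encodes |b_k|, sector fill its sign; point
distance encodes |loading|, point shape its sign.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `fraction` | 0.10 | nonzero-loading budget as a share of block size; rounded half to even with floor 1, so every block keeps at least one named variable |
| `ridge` | 1e-6 | elastic-net ridge penalty; any positive value leaves the restricted fixed point's direction unchanged, so it acts as a numerical regularizer, not a tuning knob |
| `K` per layer | `"auto"` | block count; `"auto"` takes the largest drop on the merge-height scree (candidates 2..`k_max`, default cap 20), but an explicit K from dendrogram inspection is always preferable and supported |
| `ties` | `"efron"` | Cox tie correction (Breslow available); with no tied event times they agree exactly |
| `eval_time` | KM median | ROC horizon; the Kaplan–Meier median is used rather than the raw median of observed times because censored observations bias the raw median downward |
| `censoring` (generator) | 0.2 | target censoring fraction, calibrated by bisection of the censoring-exponential rate against the subjects' realized hazard rates |
| `a` (generator) | 0.9 | within-block factor loading; gives within-block correlation a² = 0.81, a strongly blocked regime in which block recovery should be essentially exact |

## Numerical choices

* **Eigen-solver.** λ₁ and its vector come from dense symmetric
  eigendecomposition up to 512 variables and power iteration (tolerance
  1e-10, 1000 iterations) above; the two paths are tested for agreement.
* **Merge tie-break.** Candidate merges within 1e-12 of the minimal
  dissimilarity are resolved by the lowest smallest-member index, then
  the lowest second index, making the tree deterministic.
* **Sparse-PC optimizer.** The alternating updates (α from the rank-1
  fit; β from ridge regression hard-thresholded to the top-k magnitudes
  and re-solved on that support; convergence when the support is stable
  and loadings move < 1e-8, cap 500 iterations) are a greedy
  coordinate scheme and can stall in a local optimum of the implied
  support-selection problem. The support is therefore refined by a
  deterministic 1-swap local search on λ₁ of the support's correlation
  submatrix, and on small blocks (p ≤ 12, where the cost is trivial and
  local optima proportionally most harmful) additionally seeded by
  greedy forward construction from every variable. The final loadings
  are the alternating fixed point restricted to the chosen support,
  i.e. the constrained first PC of that submatrix — so the reported
  explained variance is exactly λ₁ of the support.
* **Scree confidence.** The automatic K is flagged low-confidence
  unless the best scree drop exceeds three times the runner-up drop.
  The factor was calibrated on simulations: on independent (structureless)
  variables the largest/second-largest drop ratio rarely exceeds 3,
  while planted block structure at a = 0.9 yields ratios of 5–24.
* **Stepwise.** Starts from the full model, direction both; at each
  step all single drops (label order) then single adds (label order)
  are scored and the first minimal-AIC move is taken if it improves AIC
  by more than 1e-8 — a deterministic tie-break. Moves whose fit fails
  (collinearity, monotone likelihood) are skipped.
* **CD-ROC estimator.** Censoring is handled by inverse probability of
  censoring weighting: case i (event by t) gets weight 1/G(T_i⁻) with G
  the Kaplan–Meier estimate of the censoring survival function;
  control weights are constant and cancel. With zero censoring the
  estimator reduces to the empirical ROC, whose trapezoidal AUC equals
  the Mann–Whitney statistic — this equivalence, not agreement with any
  particular published routine, is the package's correctness surface.
* **Concordance ties.** Marker ties in comparable pairs count one half
  (the usual convention); `ties = "strict"` scores them zero,
  reproducing the bare indicator-function formula.
* **Degenerate inputs.** Constant columns, missing values, duplicate
  IDs, disjoint sample sets, all-censored outcomes and
  never-reaching-0.5 KM curves are all rejected with named errors
  rather than silently handled.
* **Chart jitter.** Angular only (radius carries meaning), uniform in
  the middle 80% of the sector, from a small dedicated linear
  congruential generator so chart rendering never perturbs the global
  RNG stream. Point radii are normalized against loading magnitude 1
  and capped at the sector's own radius, keeping points inside their
  sector.

## What the synthetic generator does and does not emulate

`generate_study()` draws, per block, a standard-normal latent factor and
variables a·f + √(1−a²)·ε; blocks are independent within and across
layers. Survival times are exponential with rate h₀·exp(Σ β_k f_k) —
the proportional-hazards model with constant baseline — and censoring
times are exponential with a rate calibrated to the target censoring
fraction. Because the hazard depends on the *factors*, recovering the
planted blocks, their components, and the hazardous subset is a fair
test of the entire chain, and an exponential baseline gives closed-form
sanity checks (all β = 0, h₀ = 1 makes observed times standard
exponential).

The generator deliberately does **not** emulate marginal distributions
of real omics assays (bounded methylation beta values, count-like
expression), overlapping or correlated blocks, layer-specific noise, or
informative censoring. Passing tests therefore demonstrate correctness
of the algorithms under the model they assume, not robustness of the
pipeline to real-data violations of that model.

## Test problem sizes

The validation suite exercises: exhaustive-oracle equivalence of the
greedy agglomeration (100 random structures, p ≤ 6), of the sparse
component (100 random structures, p ≤ 8, k ≤ 3, against all C(p,k)
supports) and of the concordance index (200 random datasets, n ≤ 12);
analytic limits (k = p sparse PC vs PC1, zero-censoring AUC vs
Mann–Whitney, two-variable homogeneity 1 + |r|); and whole-pipeline
recovery on 50 generator seeds at n = 300 with nine size-30 blocks in
three layers, three of them hazardous (|β| = 0.5, 20% censoring), where
clustering recovers every planted partition exactly and stepwise
selection returns all hazardous blocks with at most one false positive
in at least 80% of seeds. These sizes were chosen so the whole suite
runs in about a minute on one core while still covering every
code path with an independent oracle.

## Known limitations

* Only the first sparse component per block is extracted; a block
  carrying two outcome-relevant factors will be summarized by one.
* The stepwise search is greedy and inherits AIC's liberal selection;
  in the recovery simulations it admits one spurious component in
  roughly a fifth of runs.
* Apparent (resubstitution) performance only: no cross-validation or
  optimism correction is built in, so reported AUC/C-index on the
  training data are optimistic for generalization.
* Exact dendrogram equality with other homogeneity-clustering
  implementations is not promised: tie-breaking and eigen-solver
  details differ across implementations, and the merge heights here are
  reported on the homogeneity-loss scale.
* Quantitative variables only; no missing-value support (impute
  upstream); no qualitative/mixed-type extension.
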