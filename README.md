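# bspcox

Block-wise sparse principal components for multi-omics survival
prediction.

High-dimensional omics studies (DNA methylation, mRNA expression, miRNA
expression, ...) routinely carry hundreds to thousands of variables per
layer for a few hundred patients, and a clinician ultimately wants a
prognostic model built from a handful of interpretable signals. `bspcox`
implements a two-stage pipeline for that task:

**Stage 1 — blockwise components per omics layer.**
Each layer X (n samples × p standardized variables) is partitioned into
homogeneous variable blocks by agglomerative clustering on the
first-eigenvalue homogeneity criterion. The homogeneity of a cluster C
is

    H(C) = λ₁(C) = Σ_{x ∈ C} r(x, l)²

where λ₁ is the largest eigenvalue of the cluster's correlation matrix
and l its synthetic variable (first principal component) — the vector
most correlated with all member variables. Clusters A and B are merged
greedily by the smallest homogeneity loss

    d(A, B) = λ₁(A) + λ₁(B) − λ₁(A ∪ B) ≥ 0,

and the tree is cut into K blocks (chosen from the scree of merge
heights, or fixed per layer). Each block is then summarised by its
**first sparse principal component**: the elastic-net reconstruction
problem

    min_{α, β} Σᵢ ‖xᵢ − α β′xᵢ‖² + λ‖β‖²,  ‖α‖ = 1,

solved with the number of nonzero loadings fixed at 10% of the block's
variables (rounded half to even, floor one), giving the component score
sPC = Xβ̂ / ‖β̂‖ supported on a short, named list of variables.

**Stage 2 — integration, Cox model, evaluation, chart.**
The per-layer component scores are concatenated in parallel into one
n × K* dataset and entered into a Cox proportional-hazards model

    h(t) = h₀(t) · exp(b₁ sPC₁ + ... + b_{K*} sPC_{K*}),

pruned by bidirectional stepwise selection on AIC. The fitted risk score
η = Σ b_k sPC_k is evaluated with cumulative/dynamic time-dependent ROC
curves (censoring handled by inverse-probability-of-censoring weights
from the Kaplan–Meier estimate of the censoring distribution; horizon
defaults to the Kaplan–Meier median survival time) and with Harrell's
concordance index. Results are drawn as a two-level polar chart: one
equal-angle sector per selected component (radius ∝ |b_k|, fill by
sign) containing one point per retained variable (distance ∝ |loading|,
shape by sign).

A synthetic-data module generates multi-omics layers with known block
structure (one latent factor per block, variable = a·factor + noise) and
survival times whose log-hazard is linear in a chosen subset of the
factors, so every stage of the pipeline can be validated against ground
truth.

## Worked example

Simulate a 215-patient, three-layer study with seven planted blocks, of
which four (D1, D3, MR1, MI2) truly drive the hazard, then run the full
pipeline:

```r
library(bspcox)

cfg <- synthetic_config(
  n           = 215,
  block_sizes = list(c(40, 30, 30), c(35, 25), c(20, 20)),
  a           = 0.8,                              # within-block loading
  beta        = c(0.5, 0, -0.5, 0.4, 0, 0, -0.4), # per-block log-hazards
  censoring   = 0.3,
  layer_ids   = c("D", "MR", "MI"),
  seed        = 20)
study <- generate_study(cfg)

run <- run_pipeline(pipeline_config(
  layers   = list(list(matrix = study$layers$D,  label = "D",  K = 3),
                  list(matrix = study$layers$MR, label = "MR", K = 2),
                  list(matrix = study$layers$MI, label = "MI", K = 2)),
  survival = study$survival,
  variant  = "bspc",
  seed     = 11))

print(run$selection$fit)
#> cox_fit: 4 covariates, 162/215 events, logPL -711.973, AIC 1431.945
#>           coef         se        HR        p
#> D1   0.1778873 0.04540280 1.1946907 8.93e-05
#> D3  -0.2968550 0.05406816 0.7431518 4.01e-08
#> MR1  0.1994272 0.04949139 1.2207034 5.59e-05
#> MI2 -0.1580271 0.05905999 0.8538267 7.46e-03

str(run$metrics)
#> List of 3
#>  $ auc    : num 0.77
#>  $ c_index: num 0.694
#>  $ t_eval : num 0.52
```

Stepwise AIC kept exactly the four hazardous blocks. The report table
(`run$table`) adds block sizes and retention: e.g. component D1 keeps 4
of its 40 variables (the 10% rule), with hazard ratio exp(0.178) = 1.19
per unit of component score. The risk score discriminates
above/below-median survivors with AUC 0.77 at the Kaplan–Meier median
horizon t = 0.52, and orders survival times with concordance 0.69.
`run$chart_spec` holds the polar-chart geometry; `render_mpchart()`
writes it as SVG.

Setting `out = "run1"` in `pipeline_config()` additionally writes
`blocks_*.tsv`, `loadings.tsv`, `integrated.tsv`, `cox_table.tsv`,
`metrics.json`, `roc.tsv`, `mpchart.svg` and a `run.log`.

Comparison variants: `variant = "pca_blocks"` replaces each sparse
component by the block's ordinary first PC (all variables loaded);
`variant = "pca_noclust"` skips clustering and uses the leading PCs of
each whole layer.

## Command-line use

Thin wrappers over the same functions are installed under
`system.file("scripts", package = "bspcox")`:

```sh
Rscript bspcox-simulate.R --config sim.yaml --out study
Rscript bspcox-run.R --config run.yaml --variant bspc --seed 11 --out run1
Rscript bspcox-chart.R --model run1/model.json --loadings run1/loadings.tsv --out mpchart.svg
```

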