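# zinbmix

Model-based clustering and batch-effect correction for single-cell
RNA-seq count matrices, in pure R.

## The problem and the model

Clustering scRNA-seq data is confounded by two technical artifacts:
dropout (excess zeros from failed transcript capture) and batch
effects. zinbmix addresses both inside one generative model instead of
as preprocessing steps. Each cell `n` has a low-dimensional biological
representation `z_n` and a positive scaling factor `t_n`
(depth/capture):

- `z_n ~ Σ_c π_c N(μ_c, I)` — a Gaussian mixture with identity
  covariances: cluster structure is part of the prior;
- `log t_n ~ N(μ̄_b, σ̄²_b)` — per-batch empirical log-library prior;
- counts `x_ng ~ ZINB(t_n ρ_ng, θ_g, α_ng)`, where the mean fractions
  `ρ` (softmax over genes) and dropout probabilities `α` are produced
  by neural decoders conditioned on `z_n` *and* the batch label, and
  `θ_g` are gene-wise inverse dispersions.

Inference is amortized variational: encoder networks output Gaussian
posteriors for `z` and `log t`; training interleaves reparameterized
minibatch Adam ascent on the evidence lower bound (backpropagation is
hand-written and finite-difference verified) with EM updates of the
mixture weights and means — a coordinate-descent scheme. Cells are then
clustered either by maximum mixture responsibility at the encoded mean
(`assign_builtin`) or by Louvain community detection on a
shared-nearest-neighbour graph of the encodings (`assign_louvain`).

The package also ships a splat-style count simulator (grouped cells,
lognormal DE factors, logistic dropout, multiplicative batch factors),
the evaluation metrics (ARI, NMI, KNN-region KL divergence of batch
mixing), Matrix Market / CSV / 10x-style readers and a CLI. See the
methods vignette (`vignettes/zinbmix-methods.Rmd`) for the full model,
the initialization strategy and the design decisions.

## Worked example

```r
library(zinbmix)

sc  <- simulation_scenario(n_cells = 300, n_genes = 200, n_groups = 3,
                           dropout_mid = -1.5, seed = 42)
ds  <- simulate_counts(sc)
ds
#> count_dataset: 300 cells x 200 genes, 1 batch(es), 3 true groups

fit <- fit_zinbmix(ds, n_components = 3,
                   training_config(max_epochs = 80, seed = 1))
fit
#> zinbmix_fit: 200 genes, 1 batch level(s), C = 3, d = 10, 80 epoch(s) run

res <- assign_builtin(fit, ds)
res
#> clustering_result (builtin): 300 cells in 3 cluster(s)

ari(res$labels, ds$true_labels)   # 0.829
nmi(res$labels, ds$true_labels)   # 0.774
round(fit$prior$pi, 3)            # 0.349 0.330 0.321
```

The three mixture weights land near the true balanced proportions
(1/3 each) and the labels agree with the simulated ground truth at
ARI 0.83 after this deliberately short 80-epoch fit; longer fits on
larger simulations reach ARI above 0.9 (see the acceptance script
below). `encode(fit, ds)$mu_z` returns the batch-corrected embedding
for downstream use.

## Command line

```sh
exec/zinbmix simulate --out sim/ --cells 500 --genes 300 --groups 3 --seed 1
exec/zinbmix fit --counts sim/counts.mtx --components 3 --out fit.rds
exec/zinbmix cluster --checkpoint fit.rds --counts sim/counts.mtx \
    --method both --out labels
exec/zinbmix evaluate --labels labels_builtin.tsv --truth sim/labels.tsv \
    --out metrics.json
exec/zinbmix reproduce-sim --out study/ --seed 1
```

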