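# gdesce

Grid-filtered deep embedded clustering with label entropy for single-cell
RNA-seq data.

`gdesce` is for analysts clustering UMI count matrices who need two nuisances
handled inside the clustering itself rather than as separate preprocessing:
isolated outlier cells, which distort centroid-based methods, and batch
effects, which masquerade as biology. The pipeline

1. normalizes counts (library-size scaling to 10,000, `log1p`, per-gene —
   optionally per-batch — standardization) and selects highly variable genes
   by binned dispersion;
2. removes low-density outlier cells on a 2-D grid: a point in a sparsely
   occupied grid cell is purged when it lies farther than half a grid-cell
   diagonal from the nearest dense cell's center, iterating until no further
   outliers are detected;
3. learns a feature space with a layer-wise pretrained, fine-tuned stacked
   autoencoder (ReLU interior, tanh bottleneck and decoder);
4. seeds K and the centroids by Louvain community detection on a
   shared-nearest-neighbour graph of the bottleneck features; and
5. iteratively refines encoder and centroids by minibatch SGD on a
   squared-target-weighted KL objective.

The core objective couples the Student's-t soft assignment
*s*<sub>ij</sub> = (1 + ‖f<sub>i</sub> − k<sub>j</sub>‖²/α)<sup>−1</sup> / Σ<sub>j′</sub> (·)
with a sharpened auxiliary target
*t*<sub>ij</sub> ∝ s<sub>ij</sub>² / Σ<sub>i</sub> s<sub>ij</sub> and minimizes

&nbsp;&nbsp;&nbsp;&nbsp;L = Σ<sub>i</sub> Σ<sub>j</sub> t<sub>ij</sub>² log( t<sub>ij</sub> / s<sub>ij</sub>² ),

a label-entropy-motivated reweighting of the classic deep-embedding
self-training loss: the t² factor concentrates the optimization on
confidently assigned cells. Iteration stops when the fraction of cells whose
hard label changed falls below a tolerance (default 0.005). Shipped metrics:
exact adjusted Rand index, a per-cluster KL-divergence batch-mixing score,
and per-cell label entropy. A negative-binomial generator plants clusters,
batch shifts and outliers so everything is testable offline.

## Worked example

```r
library(gdesce)

sim <- generate_cells(synthetic_config(seed = 0))
sim$counts
#> <count_matrix> 2000 cells x 500 genes, 2 batches, 4 truth labels

fit <- gdesce(sim$counts, gdesce_config(seed = 0))
fit
#> <gdesce_fit> 2000 cells (142 removed as outliers), K = 3, 12 epoch(s)

metrics_report(fit)
#> <metrics_report>
#>   ARI            0.9678
#>   batch KL       0.0003
#>   mean entropy   0.6698
#>   cells 2000 (outliers removed 142), K = 3, epochs = 12

glance(fit)
#> # A tibble: 1 x 7
#>   n_cells n_outliers_removed     K n_epochs final_loss final_tol mean_entropy
#>     <int>              <int> <int>    <int>      <dbl>     <dbl>        <dbl>
#> 1    2000                142     3       12       846.   0.00323        0.758
```

The generator planted 3 clusters, 2 batches and 5% outliers in 2000 cells.
The grid filter removed 142 cells (the 100 planted outliers plus a thin
fringe), Louvain seeded the centroids, and 12 epochs of self-training
recovered the planted partition with ARI 0.97 against the planted labels,
near-zero batch KL (clusters mirror the global batch mix), and a mean label
entropy of 0.67 — most cells assigned with high confidence. `tidy(fit)` gives
one row per cell (label, 2-D coordinates, assignment probability),
`autoplot(fit)` draws the embedding, `plot_traces(fit)` the per-epoch loss,
tolerance and entropy.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/gdesce.R simulate --out sim/ --seed 0
Rscript inst/cli/gdesce.R run --input sim/matrix.mtx --format mtx --out results/ --seed 0
```

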