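# scGraphImpute

Dropout imputation and cell clustering for single-cell RNA-seq, built
around an iterative set of autoencoders on a cell graph with multi-head
graph attention.

## Who this is for

scRNA-seq count matrices are dominated by zeros, many of them *dropouts* —
transcripts present in the cell but recorded as zero. scGraphImpute is for
analysts who want to (a) cluster cells on a representation that respects
cell–cell graph structure and (b) replace likely technical zeros with
model-based estimates, on matrices up to a few thousand cells.

## The model

Let X be the log-normalized cells × genes matrix. The workflow iterates:

1. **Feature autoencoder** (G → 512 → 128 → 512 → G) minimizing
   (1 − α)·Σ(X − X̂)² + α·Σ((X − X̂)² ∘ TRS), where TRS is a per-entry
   weight from a per-gene **left-truncated Gaussian mixture** (LTMG):
   observations at or below Zcut (observed zeros in log space) are treated
   as left-censored, the component count is chosen by BIC, and each entry
   is labeled with its maximum-posterior component.
2. **Cell graph**: KNN on the 128-dim embedding, per-node edge-length
   quantile pruning, GCN normalization D̃^(−1/2)(A + I)D̃^(−1/2); from
   round 2 the propagation matrix is μ·L0 + (1 − μ)·RowNorm(A_t), μ = 0.5.
3. **Graph autoencoder** with two graph-attention layers (→ 32 → 16):
   per head, e_ij = (W h_i)·(W h_j) softmax-normalized over neighbors,
   head outputs averaged; decoder Â = sigmoid(Z Zᵀ) trained by
   class-balanced cross-entropy. `heads = 0` gives the plain GCN ablation.
4. **Louvain** fixes the cluster count on the pruned graph, **k-means**
   (k-means++, 10 restarts) assigns cells on Z, and **per-cluster
   autoencoders** reconstruct the matrix that feeds the next round.

After the labels stabilize (consecutive-round ARI > 0.99) an **imputation
autoencoder** is trained once on the original matrix with the final graph
A and cell-type matrix B (B_ij = 1 iff same cluster):

Loss = (1 − α)Σ(X − X̂)² + αΣ((X − X̂)² ∘ TRS) + βΣ|w|
     + γ₁ Σᵢⱼ A_ij‖(X − X̂)ᵢ‖² + γ₂ Σᵢⱼ B_ij‖(X − X̂)ᵢ‖².

By default only observed zeros are replaced in the output. All metrics of
the trade (ARI, AMI, NMI, completeness/homogeneity/V-measure,
Fowlkes–Mallows, silhouette, Davies–Bouldin; masked-entry cosine, L1
summaries, RMSE) are implemented and oracle-tested, plus a seeded
synthetic-dropout benchmark that flips round(rate·nnz) non-zero entries to
zero and scores recovery on exactly those entries.

## Worked example

```r
library(scGraphImpute)

ds  <- generate_dataset(simulation_config(seed = 1))   # 200 x 300, 3 clusters
cfg <- sgi_config(seed = 1, min_genes_per_cell = 10, n_top_genes = 300)
pp  <- cmd_preprocess(ds$counts, NULL, cfg)            # filter, log, LTMG/TRS
res <- run_iterative_pipeline(pp$matrix, pp$trs, cfg)

iteration_history(res$state)
truth <- ds$truth$labels[match(pp$matrix$cell_ids, ds$counts$cell_ids)]
ari(truth, res$assignment$labels)
```

```
  round k adjacency_delta label_ari_prev feature_loss  gae_loss cluster_sizes
1     1 3              NA             NA   23722.8072 0.9739021      67/67/66
2     2 3       0.4275359              1    1602.5279 0.9269292      67/67/66
3     3 3       0.2884132              1     880.4035 0.9187898      67/67/66
[1] 1
```

Louvain finds k = 3 in round 1; the labels are already stable from round 2
(`label_ari_prev = 1`) and the run stops in round 3 when the propagation
matrix has also stabilized. The final adjusted Rand index against the
planted labels is 1: every cell is assigned to its generating cluster.
`res$imputed_zeros` holds the expression matrix with observed zeros
replaced by the imputation autoencoder's reconstruction.

A command-line front end with `simulate`, `preprocess`, `run` and
`benchmark` subcommands (flags `--heads`, `--no-gae`, `--quantile`,
`--mu`, ...) is installed at `inst/cli/scgraphimpute.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/scgraphimpute.R", package="scGraphImpute"))')" \
    simulate --out sim_out --seed 1
```

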