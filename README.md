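# stdcl

Spatial-domain identification for spatial transcriptomics by **dual graph
contrastive learning**: an R implementation of a graph convolutional
autoencoder that fuses spatial coordinates and gene expression into one
neighbor graph and trains the embedding under two contrastive objectives.

## Who this is for

Analysts of spot-based (10x Visium, Stereo-seq) or imaging-based (MERFISH,
STARmap, osmFISH) spatial transcriptomics data who need to partition spots
into contiguous spatial domains (e.g. cortical layers), denoise expression,
and rank the genes that drive the learned embedding — plus the
formula-faithful metrics to evaluate all of it.

## The method

Given a spots × genes count matrix $X$ and spot coordinates, the package:

1. **Preprocesses** — library-size normalization to the median total,
   $\log(1+x)$, top-3000 highly-variable-gene selection, per-gene z-scoring.
2. **Builds the fused graph** — spatial kNN and expression kNN adjacencies
   ($k_1 = k_2 = 3$, Euclidean), combined as
   $A = \min(A^{spatial} + \alpha A^{gene}, 1)$ with $\alpha = 0.5$, and
   GCN-normalized as $P = D^{-1/2}(A+I)D^{-1/2}$.
3. **Trains a one-hidden-layer graph convolutional autoencoder**
   $Z = \sigma(P X W_e)$, $H = P Z W_d$, $\hat A = \mathrm{sigmoid}(ZZ^\top)$
   under the total loss

   $$L = \gamma_1 L_{rec} + \gamma_2 L_{con} + \gamma_3 L_{clu},
   \quad (\gamma_1,\gamma_2,\gamma_3) = (10, 0.5, 0.8),$$

   where $L_{rec}$ reconstructs expression and adjacency
   ($\alpha_1 = 1, \alpha_2 = 0.5$), $L_{con}$ is the MSE between the
   cross-view spot cosine-similarity matrix and $A$ (the corrupted view is
   $X$ times elementwise Gaussian noise), and $L_{clu}$ pushes the
   cross-view feature cosine matrix of group-averaged embeddings toward the
   identity. Two-phase Adam: 500 pre-training epochs (lr 0.001,
   reconstruction only), 1000 training epochs (lr 0.005, full loss).
4. **Clusters and refines** — PCA to 20 components, Gaussian mixture
   (mclust, shared covariance) at known k or Leiden otherwise, selection
   between two corruption-noise runs (sd 0.1 / 0.2) by Davies–Bouldin
   index, then majority-vote label refinement within spatial radius
   $r = 50$.
5. **Interprets** — latent-15-NN expression denoising and gene ranking by
   the standard deviation of each gene's encoder-weight row.

All metrics (ARI, NMI, homogeneity, DBI, PCC/MSE/SRCC/cosine) are
implemented directly from their defining formulas and validated against
independent brute-force oracles in the test suite.

## Worked example

Simulate a 4-layer striped tissue (800 spots × 200 genes, negative-binomial
counts, 10 marker genes per domain) and recover its domains:

```r
library(stdcl)

ds <- generate_dataset(tissue_preset("easy"), seed = 0)
ds
#> <spatial_dataset> 800 spots x 200 genes, 4 labelled domains

cfg <- train_config(pretrain_epochs = 100, train_epochs = 200, seed = 0)
res <- stdcl_run(ds, k = 4, cfg = cfg, refine_radius = 150)
res
#> <stdcl_result> 800 spots, k = 4 domains, DBI = 0.521 (noise sd 0.1)

adjusted_rand_index(ds$labels, res$labels_refined)
#> [1] 0.9932445
```

The refined labels agree with the simulated ground truth at ARI 0.993 —
essentially perfect recovery, with the residual disagreement on stripe
boundaries. `tidy(res)` gives a per-spot tibble, `glance(res)` a one-row
summary, `autoplot(res)` the domain map, and `plot_loss_history(res)` the
three loss components per epoch. Downstream:

```r
den <- denoise_expression(normalize_log(ds), res$embedding, k = 15)
top <- interpretable_gene_ranking(res$model, top_m = 20,
                                  gene_ids = ds$gene_ids)
```

A command-line front end wrapping these functions is at
`inst/cli/stdcl.R` (subcommands `simulate`, `preprocess`, `run`,
`evaluate`, `denoise`, `genes`).

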