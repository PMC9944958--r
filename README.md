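# dmlalign

Batch alignment of multi-batch single-cell RNA-seq by over-clustering,
nearest-neighbour–guided cluster merging, and deep metric learning — built
for the situation where naive "correct first, cluster later" pipelines
lose rare or batch-unique cell types.

## Who this is for

Anyone integrating cells × genes count matrices from several batches
(labs, protocols, donors, species) who cares about recovering *all*
populations, including ones present in a single batch, and wants a
batch-corrected low-dimensional embedding plus cluster labels with a fully
auditable merge trace.

## The method

1. **Preprocess**: filter (nGene ≥ 10, nCells ≥ 3) → per-cell total-count
   normalization to 10,000 and log1p → highly variable genes (batch-aware
   normalized dispersion, default 1,000) → per-batch z-scaling truncated at
   ±10 → PCA (100 components).
2. **Over-cluster**: Louvain at resolution 3.0 on an SNN graph of the PCA
   embedding — deliberately too fine, so every initial cluster is pure.
3. **NN pairs**: intra-batch symmetrized KNN pairs (cosine, k_in = 5) and
   inter-batch mutual nearest neighbours (cosine, k_bw = 10).
4. **Merge**: cluster similarity s(i, j) = a(i, j) / min(m_i, m_j), where
   a counts ordered NN pairs between clusters i, j and m are cluster
   sizes; greedy agglomeration by maximal similarity; the number of
   clusters is inferred from the eigengap of the normalized similarity or
   supplied; final labels are connected components of the merge graph.
5. **Embed**: a small MLP (input → 256 ReLU → 32) trained with Adam on the
   triplet loss max(d(a, p) − d(a, n) + 0.2, 0), mining all hard triplets
   (negative closer to the anchor than the positive) within label-balanced
   minibatches, supervised by the merged labels. Batch identity is never
   shown to the trainer.

Six benchmark metrics ship with the package — ARI, NMI, silhouette by cell
type and by batch, iLISI and BatchKL — plus a splatter-style multi-batch
negative-binomial simulator with rare types, batch-unique types and nested
subtypes, so the whole pipeline is testable offline.

## Worked example

```r
library(dmlalign)

# benchmark design: 3 batches x 6 types (~2,880 cells x 2,000 genes),
# one rare type (~2%), one type present only in batch 1, strong batch effect
sim <- simulate_batches(seed = 1)
fit <- integrate_batches(sim, seed = 1, verbose = TRUE)
#> stage 2/5: initial clustering (resolution 3.0)
#>   14 initial clusters
#> stage 3/5: NN pair search (k_in = 5, k_bw = 10)
#>   49896 ordered pairs (21860 intra, 28036 inter)
#> stage 4/5: similarity + merge
#>   candidate cluster numbers: [6]; merging to K = 6

ari(sim$cell_type, fit$final_labels)
#> [1] 0.9994848
nmi(sim$cell_type, fit$final_labels)
#> [1] 0.9986385

evaluate_integration(fit$embedding, fit$final_labels, sim$batch,
                     truth = sim$cell_type, seed = 1)
#> # A tibble: 1 x 6
#>     ari   nmi asw_celltype asw_batch ilisi batchkl
#>   <dbl> <dbl>        <dbl>     <dbl> <dbl>   <dbl>
#> 1 0.999 0.999        0.816     0.499  2.36   0.101
```

The 14 batch-confounded initial clusters (labelling cells by them scores
ARI ≈ 0.46 against truth) merge into exactly the 6 true types; the
batch-unique type keeps its own cluster; iLISI rises from ≈ 1.4 in the
uncorrected PCA towards the batch count 3, and BatchKL falls from ≈ 0.37
to ≈ 0.10, i.e. the learned embedding mixes batches while separating
types.

`tidy(fit)` gives a per-cell tibble, `glance(fit)` a one-row summary,
`plot_integration(fit, colour = "batch")` a ggplot of the embedding. A
thin command-line wrapper with `simulate` / `preprocess` / `integrate` /
`evaluate` subcommands lives at `inst/cli/dmlalign.R`, and
`vignettes/batch-alignment-methods.Rmd` documents the model, parameters
and design choices.

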