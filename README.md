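# ssre

Cell-type identification from single-cell RNA-seq expression matrices by
**similarity learning**. Instead of scoring cells two at a time, each cell is
written as a sparse linear combination of all other cells — the sparse
subspace representation — so that similarity is certified by a whole
neighborhood of same-type cells. The learned affinity is refined by
Laplacian-score gene selection under four similarity graphs and by a
weighted common-neighbor (Adamic/Adar) imputation of edges the sparse model
missed, then clustered spectrally with eigengap estimation of the number of
clusters.

The package is aimed at analysts clustering scRNA-seq matrices of roughly
50–5000 cells (counts, FPKM, TPM — any nonnegative unit), and at method
developers who want the individual stages (solver, gene scoring,
enhancement, metrics, simulator) as separately testable functions.

## The model

With `X` the genes-by-cells matrix, each cell L2-normalized, the coefficient
matrix solves

```
min_C  (w/2) ||X - XC||_F^2 + ||C||_1   s.t.  diag(C) = 0,
```

by ADMM, with the data weight `w` set adaptively from the cosine-similarity
Gram matrix `M = X'X`: `w = (rho/lambda) / rho`, `rho = min_j max_{i≠j} M_ij`,
and `rho/lambda = 10` by default. The affinity is `S_ij = |c_ij| + |c_ji|`.
Informative genes are kept by intersecting, across the sparse affinity and
Pearson/Spearman/cosine graphs, the genes with the best Laplacian scores
(`(f'Lf)/(f'Df)`, low = marker-like), split from the rest by an exact
variance-minimizing threshold constrained to select between 10% and 50% of
genes. Zero affinities ranked as k-nearest neighbors by a classical
similarity are imputed from common neighbors, and the enhanced matrix
`E = I + I' + S` feeds symmetric normalized-Laplacian spectral clustering.

## Worked example

```r
library(ssre)

# three groups, proportions 0.65/0.25/0.10, dropout calibrated to 61% zeros
cfg <- calibrate_dropout(sim_config(n_cells = 500, seed = 1), 0.61)
sim <- simulate_counts(cfg)
res <- run_pipeline(sim$counts, ssre_config(K = "auto", seed = 1),
                    true_labels = sim$labels)
print(res)
```

```
SSRE clustering of 500 cells
  selected genes: 165  | enhancement k: 50  imputed edges: 26940 
  K used: 3  (eigengap estimate: 3 )
cluster
  1   2   3 
 53 330 117 
  NMI: 0.9862  ARI: 0.9939 
```

The eigengap found the three planted groups without being told `K`, and the
clustering agrees with the simulated labels almost perfectly (ARI 0.994),
including the 10% minority population of 53 cells. Downstream:

```r
deg <- kruskal_wallis_deg(sim$counts, res$labels)   # per-gene H and p
head(deg, 3)
```

```
   gene_id h_statistic      p_value   p_adjusted rank significant
1  gene931    248.2662 1.229336e-54 2.458673e-51    1        TRUE
2 gene1096    239.0217 1.250534e-52 1.231585e-49    2        TRUE
3 gene1273    238.2413 1.847377e-52 1.231585e-49    3        TRUE
```

```r
coords <- visualize_similarity(res$E, labels = res$labels, seed = 1, plot = TRUE)
```

A thin command-line front end covers the same steps
(`exec/ssre run|simulate|deg|viz`); see `vignettes/ssre-methods.Rmd` for the
model details, parameter meanings, and design decisions.

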