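# scStateImpute

Dropout imputation for single-cell RNA-seq expression matrices that
combines **cell-level**, **gene-level**, and **transcriptome-dynamic**
information. Dropouts — transcripts present in a cell but missed by
capture and sequencing — inflate the zero fraction of scRNA-seq count
matrices and distort expression distributions, gene–gene correlations and
every downstream analysis. Methods that borrow only from similar cells
over-smooth; methods that borrow only from correlated genes amplify
spurious signal. scStateImpute blends both, and decides per entry how much
to trust either, with an explicit dropout-probability model. It is aimed
at anyone preparing a genes × cells count matrix (10x MatrixMarket or
dense CSV/TSV) for trajectory, clustering or differential-expression
analysis.

## The method

On the log-CPM matrix $x_{ij} = \log_2(10^6 x^C_{ij} / \sum_k x^C_{kj} + \theta)$:

1. **Cell-state spaces.** Cells are ordered by a cluster-based
   minimum-spanning-tree pseudotime (Gaussian-mixture clusters in PCA
   space, MST over centers, projection onto the diameter path) and cut
   into consecutive spaces of $m = 5(\lceil J/10^3\rceil + 1)$ cells.
2. **Cell level.** Within each space, cell $j$ is predicted by its
   neighbors with adaptive Gaussian kernel weights
   $k_{jj'} = e^{-d_{jj'}^2/\sigma_j^2}$, $\sigma_j$ the mean distance to
   the other in-space cells → matrix $C$.
3. **Gene level.** Space-averaged *pseudo-cells* feed a per-space gene
   co-expression network built from a neighborhood-occupancy independence
   z-statistic (edges must be significant at every box fraction 0.1, 0.2,
   0.3); each gene is the $|r|$-weighted average of its network neighbors
   → matrix $G$.
4. **Dropout probability.** Per space, zero fraction vs mean expression
   is fitted with a decreasing logistic
   $p = 1 - 1/(1 + e^{a + b x})$, $b \le 0$ → matrix $P$.
5. **Combination.**
   $\hat{x}_{ij} = p_{ij}\bigl(\tfrac{\beta}{\alpha+\beta}c_{ij} + \tfrac{\alpha}{\alpha+\beta}g_{ij}\bigr) + (1-p_{ij})x_{ij}$,
   with $\alpha = \mathrm{sd}(C)$, $\beta = \mathrm{sd}(G)$. High
   observed expressions pass through untouched; only probable dropouts
   move.

The package also ships the evaluation metrics used for imputation
benchmarking (Gini coefficient, RMSE, correlation matrix distance,
pseudotemporal ordering score, Kendall's τ, ARI/Jaccard/Fowlkes–Mallows,
assignment accuracy) and ground-truthed trajectory/group simulators so
every stage is testable without downloads. See
`vignettes/multidimensional-imputation.Rmd` for the full model account.

## Worked example

```r
library(scStateImpute)

d    <- simulate_trajectory(n_genes = 500, n_cells = 200, seed = 1)
raw  <- expression_matrix(d$observed_counts)
held <- mask_entries(raw, rate = 0.2, seed = 2)   # hide 20% of nonzeros
res  <- run_pipeline(held$masked, config = list(seed = 3))
res
#> ImputationResult: 500 genes x 200 cells, 20 space(s)
#>   alpha (sd of C) = 3.439, beta (sd of G) = 3.602

mask <- held$mask
rmse(d$true_log[mask], res$imputed$values[mask])                      # 7.303
rmse(d$true_log[mask],
     log_transform(normalize_cpm(held$masked))$values[mask])          # 11.244
cor(d$true_log[mask], res$imputed$values[mask])                       # 0.643
abs(kendall_tau(order(res$pseudotime$order), rank(d$true_time)))      # 0.838
```

The held-out entries are recovered with a root-mean-square error of 7.30
log2-CPM units against 11.24 for leaving them at zero, correlate 0.64
with the dropout-free truth, and the inferred pseudotime matches the
latent simulation time at |τ| = 0.84. `res` retains every intermediate
layer (`C`, `G`, `P`, the partition, per-space logistic fits) for
auditing, and `inverse_transform(res$imputed)` returns count-scale
output.

A command-line front end with `impute`, `simulate` and `evaluate`
subcommands is installed at
`system.file("cli/scstateimpute.R", package = "scStateImpute")`.

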