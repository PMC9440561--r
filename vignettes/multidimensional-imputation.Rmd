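---
title: "Multidimensional dropout imputation along pseudotime cell states"
author: "scStateImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional dropout imputation along pseudotime cell states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scStateImpute)
```

## The problem

Single-cell RNA-seq count matrices are dominated by zeros. Some are
biological (the gene is off), but many are *dropouts*: the transcript was
present in the cell and simply missed by capture and sequencing. Dropouts
distort per-gene expression distributions, gene–gene correlations, and
every downstream analysis built on them — trajectory inference, clustering,
differential expression. Imputation methods that borrow only from similar
cells tend to over-smooth and erase heterogeneity; methods that borrow only
from correlated genes can amplify spurious signal in a sparse matrix. This
package blends both sources of information, and decides *how much* to trust
either one, per entry, with an explicit dropout-probability model.

## The model

Let $X^C$ be the $I \times J$ genes $\times$ cells count matrix. All
modelling happens on the preprocessed matrix
$$x_{ij} = \log_2\!\left(\frac{10^6\, x^C_{ij}}{\sum_k x^C_{kj}} + \theta\right),$$
counts-per-million with a pseudo-count $\theta$ (default 1, so zero counts
map to exactly 0 on the log scale).

**Cell-state spaces.** Cells are ordered along a cluster-based
minimum-spanning-tree pseudotime: PCA scores of the cells are clustered
with a full-covariance Gaussian mixture (the number of clusters chosen by
BIC over 2–9), an MST connects the cluster centers, the tree's diameter
path is the main path, and each cell is projected orthogonally onto the
polyline through the path's centers; arc-length position is its
pseudotime. The ordered matrix is cut into consecutive *cell-state
spaces* of $m = 5(\lceil J/10^3 \rceil + 1)$ cells each. Cells within a
space are treated as sharing an expression state, which is what licenses
the local borrowing below. Users with an external pseudotime can supply
the ordering directly and skip inference.

**Cell-level prediction.** Within each space, cell $j$ is predicted as a
weighted average of the *other* cells, with adaptive Gaussian kernel
weights $k_{jj'} = \exp(-d_{jj'}^2/\sigma_j^2)$, where $d$ is Euclidean
distance on the log layer and $\sigma_j$ is the mean distance from $j$ to
its in-space neighbors. The width adapts to local density: isolated cells
spread their trust more evenly, cells in dense neighborhoods concentrate
it. This yields the matrix $C$.

**Gene-level prediction.** Averaging each space's cells gives one
*pseudo-cell* per space; pseudo-cells damp dropout noise before gene–gene
association is measured. For each space we build a co-expression network
on the pseudo-cell matrix with a neighborhood-occupancy independence
statistic: around the focal pseudo-cell, take the box of the
$\lceil f S \rceil$ nearest values of each gene, and compare joint box
occupancy $n_{xy}$ against its independence expectation,
$$z = \frac{n\,n_{xy} - n_x n_y}{\sqrt{n_x n_y (n-n_x)(n-n_y)/(n-1)}}.$$
Two genes are connected only if $z$ exceeds the one-sided normal
$1-\alpha$ quantile ($\alpha = 0.01$) for *every* box fraction
$f \in \{0.1, 0.2, 0.3\}$ — dependence that appears at one neighborhood
scale but not another is discarded. Each gene is then predicted as the
$|r|$-weighted average of its network neighbors' expression in the space
($r$ the per-space Pearson correlation), giving the matrix $G$; genes with
no usable neighbors fall back to their cell-level prediction.

**Dropout probability.** Per space, the per-gene zero fraction is
regressed on the per-gene mean with a decreasing logistic curve
$z_i \approx 1 - 1/(1 + e^{a + b\mu_i})$, $b \le 0$, by nonlinear least
squares. Evaluating the fitted curve at each entry gives
$p_{ij} = 1 - 1/(1 + e^{a + b x_{ij}})$: low observations are probably
dropouts, high observations almost certainly are not.

**Combination.** The imputed value is
$$\hat{x}_{ij} = p_{ij}\left(\tfrac{\beta}{\alpha+\beta} c_{ij} +
\tfrac{\alpha}{\alpha+\beta} g_{ij}\right) + (1 - p_{ij})\, x_{ij},$$
with $\alpha = \mathrm{sd}(C)$ and $\beta = \mathrm{sd}(G)$ over all
entries: the *less* dispersed prediction layer gets the larger weight.
Because $p$ vanishes at high expression, strongly expressed entries pass
through essentially untouched — the method only rewrites entries it
believes are dropouts, and every $\hat{x}_{ij}$ lies in the interval
spanned by $\{x_{ij}, c_{ij}, g_{ij}\}$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `theta` | 1 | log pseudo-count; keeps zeros at 0 on the log scale |
| `m` | $5(\lceil J/10^3\rceil+1)$ | cells per state space; user-overridable |
| `min_last` | 3 | trailing cells merged into the previous space below this size |
| `box_fractions` | 0.1, 0.2, 0.3 | neighborhood sizes for the independence test |
| `network_alpha` | 0.01 | one-sided significance per box fraction |
| `network_genes` | 2000 | network built on this many top-variance genes |
| `cor_on` | `"cells"` | correlation weights from the space's cells (or `"pseudocells"`) |
| `k_min`, `k_max` | 2, 9 | range of mixture sizes for pseudotime clustering |

## Numerical and design choices

* **Independence statistic centering.** The focal pseudo-cell is its own
  nearest value on every axis; counting it would force one guaranteed
  joint occupant into every box and bias the null mean of $z$ upward by
  roughly half a standard deviation at $S \approx 100$. We therefore take
  the boxes over, and count occupancy among, the $S-1$ *other*
  pseudo-cells, which makes $z$ mean-zero, unit-variance under
  independence (verified by simulation in the test suite).
* **Conjunction power.** Requiring significance at every box fraction
  keeps the false-edge rate well below $\alpha$, but the smallest box
  ($\lceil 0.1 S\rceil$ values) is narrow relative to residual noise: at
  $S \approx 100$ the test connects gene pairs whose dependence is close
  to functional, not merely well-correlated. This is intentional —
  gene-level borrowing should be reserved for near-deterministic
  relationships — and genes without such partners simply fall back to the
  cell-level prediction, so network sparsity costs accuracy, not
  coverage.
* **Small partitions.** The $z$ statistic is meaningless with fewer than
  10 pseudo-cells; there the edge rule switches to
  $|\text{Pearson}| \ge 0.8$ on pseudo-cells, announced via a message.
  Likewise the last space absorbs a trailing remainder smaller than
  `min_last`, because kernel widths and per-space fits are degenerate on
  1–2 cells.
* **Correlation weights.** Network association is sign-agnostic, but a
  weighted average needs nonnegative weights, so neighbors are weighted
  by $|r|$; zero-variance genes get correlation 0 everywhere (including
  the diagonal) rather than `NA`.
* **Logistic fit.** The contract is the least-squares objective with
  $b \le 0$ and tolerance $10^{-8}$, not a particular optimizer
  (Levenberg–Marquardt with a box constraint is used). Degenerate inputs
  — constant zero fractions, fewer than five distinct means — fall back
  to $a = \mathrm{logit}(\text{overall zero fraction, clipped to }
  [0.01, 0.99])$, $b = -1$, flagged per space, never an error.
* **Determinism.** PCA component signs are fixed by the largest-magnitude
  loading; MST distance ties break lexicographically; the diameter path
  breaks ties by total length then smallest starting cluster; cells tied
  in arc position order by index; orientation is fixed by requiring the
  lowest-index cell of the first path cluster into the earlier half. The
  terminal path segments extend beyond their end centers so cells past
  the ends receive distinct positions. Identical seed and input give
  bit-identical output.
* **All-zero cells** are an error in CPM normalization, not silently
  dropped; `filter_matrix()` is the sanctioned removal path.

## The synthetic generator

`simulate_trajectory()` emulates the data the model assumes: latent cell
times $t \sim U(0,1)$; per-gene base means drawn lognormal (meanlog 0.5,
sdlog 1.2, i.e. typical means between a fraction of a count and tens of
counts); profiles mixed 40% constant, 20% linear, 20% sigmoid, 20%
transient pulse, spanning roughly ninefold amplitude (0.2–1.8 relative to
base) — the dynamic range a differentiation experiment commonly shows;
negative-binomial counts with dispersion 0.3; then dropout on the count
scale with probability $1 - 1/(1 + e^{1.5 - \log_2(\mu+1)})$, the same
decreasing-logistic law the dropout model fits, so the generator's
$(a, b) = (1.5, -1)$ are recoverable in the noiseless limit and parameter
recovery is a sharp test. `simulate_groups()` swaps the trajectory for
discrete groups with a chosen fraction of fold-changed genes, for testing
the clustering metrics. What the generator does *not* emulate: realistic
library-size variation, batch effects, doublets, or UMI saturation —
passing tests demonstrate correctness of the algorithm under its own
assumptions, not performance on any particular real dataset.

Test and verification problem sizes are deliberately desk-scale: the
end-to-end masking benchmark uses 2000 genes × 300 cells with 20% of
nonzero entries held out, pseudotime recovery uses 500 genes × 200 cells,
and the statistic calibrations use 100–200 pseudo-cells and 300–500
simulated pairs.

## A small run

```{r example, eval = FALSE}
d <- simulate_trajectory(n_genes = 500, n_cells = 200, seed = 1)
raw <- expression_matrix(d$observed_counts)
held <- mask_entries(raw, rate = 0.2, seed = 2)
res <- run_pipeline(held$masked, config = list(seed = 3))

mask <- held$mask
rmse(d$true_log[mask], res$imputed$values[mask])          # imputed error
rmse(d$true_log[mask], log_transform(normalize_cpm(held$masked))$values[mask])
```

## Known limitations

* A single linear ordering: branching trajectories are collapsed onto the
  MST diameter path, so side branches are ordered by their projection
  onto the main path.
* The network step is $O(I^2 S)$ per space; beyond `network_genes` genes
  it restricts itself to the top-variance subset and falls back to
  cell-level predictions elsewhere.
* The dropout curve is shared by all genes in a space; genes whose zeros
  are mostly biological at intermediate expression will have them partly
  imputed toward the neighborhood consensus.
* CPM-per-cell normalization assumes library size is nuisance; strong
  composition effects are not corrected.
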