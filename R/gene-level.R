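#' Pseudo-cell matrix
#'
#' Averages expression across the cells of each space, producing one
#' pseudo-cell column per space. Pseudo-cells damp the effect of dropouts
#' on gene-to-gene association estimates.
#'
#' @param X Genes x cells log-layer matrix (original cell order).
#' @param partition A [partition_cells()] result.
#' @return Genes x S matrix `Xbar`.
#' @export
build_pseudocells <- function(X, partition) {
  X <- as.matrix(X)
  Xbar <- vapply(partition$blocks,
                 function(idx) rowMeans(X[, idx, drop = FALSE]),
                 numeric(nrow(X)))
  Xbar <- matrix(Xbar, nrow = nrow(X),
                 dimnames = list(rownames(X),
                                 paste0("space", seq_len(partition$S))))
  Xbar
}

# Box membership among the non-focal pseudo-cells: the box around
# xbar_row[s] whose half-width is the k-th smallest |difference| to the
# other pseudo-cells (ties at the boundary included). Excluding the focal
# pseudo-cell from the counts keeps the statistic mean-zero under
# independence; including it forces one guaranteed joint occupant and a
# positive null bias.
csn_box <- function(xbar_row, s, k) {
  d <- abs(xbar_row - xbar_row[s])
  h <- sort.int(d[-s], partial = k)[k]
  (d <= h)[-s]
}

#' Neighborhood-occupancy independence statistic for one gene pair
#'
#' Centered at pseudo-cell `s`: over the `n = S - 1` other pseudo-cells,
#' `n_x` counts those whose gene-`i` value lies in the box of
#' `ceiling(box_fraction * S)` nearest values around gene `i`'s value at
#' `s` (`n_y` analogously for gene `i2`), and `n_xy` counts those in both
#' boxes. The statistic
#' `z = (n*n_xy - n_x*n_y) / sqrt(n_x*n_y*(n-n_x)*(n-n_y)/(n-1))`
#' is approximately standard normal when the genes are independent, and
#' large positive when joint box occupancy exceeds its independence
#' expectation. Degenerate boxes (`n_x` or `n_y` in `{0, n}`, e.g. a
#' constant gene) return 0.
#'
#' @param Xbar Genes x S pseudo-cell matrix.
#' @param s Focal space (pseudo-cell) index.
#' @param i,i2 Gene row indices.
#' @param box_fraction Box size as a fraction of `S`, in (0, 1).
#' @return Scalar z-value.
#' @export
csn_statistic <- function(Xbar, s, i, i2, box_fraction) {
  S <- ncol(Xbar)
  if (S < 10)
    stop("need >= 10 pseudo-cells for the independence statistic; ",
         "use the correlation fallback for small S")
  if (box_fraction <= 0 || box_fraction >= 1)
    stop("box_fraction must be in (0, 1)")
  k <- ceiling(box_fraction * S)
  bx <- csn_box(Xbar[i, ], s, k)
  by <- csn_box(Xbar[i2, ], s, k)
  n <- S - 1
  nx <- sum(bx); ny <- sum(by); nxy <- sum(bx & by)
  if (nx == 0 || nx == n || ny == 0 || ny == n) return(0)
  (n * nxy - nx * ny) / sqrt(nx * ny * (n - nx) * (n - ny) / (n - 1))
}

# Vectorized z matrix over all gene pairs for one focal space and one
# box fraction. Same box/count rules as csn_statistic.
csn_z_matrix <- function(Xbar, s, box_fraction) {
  S <- ncol(Xbar)
  k <- ceiling(box_fraction * S)
  D <- abs(Xbar - Xbar[, s])
  Dn <- D[, -s, drop = FALSE]
  h <- apply(Dn, 1, function(d) sort.int(d, partial = k)[k])
  B <- (Dn <= h) * 1
  n <- S - 1
  nx <- rowSums(B)
  nxy <- tcrossprod(B)
  num <- n * nxy - outer(nx, nx)
  den <- sqrt(outer(nx * (n - nx), nx * (n - nx)) / (n - 1))
  z <- num / den
  z[!is.finite(z)] <- 0
  bad <- nx == 0 | nx == n
  z[bad, ] <- 0
  z[, bad] <- 0
  z
}

#' State-specific gene co-expression network
#'
#' Two genes are connected iff their independence z-value exceeds the
#' one-sided normal quantile `z_(1-alpha)` for *every* box fraction — the
#' conjunction over differently sized neighborhoods guards against local
#' (box-size specific) dependence artefacts. Requires at least 10
#' pseudo-cells; for fewer, see the correlation fallback used by
#' [gene_level_matrix()].
#'
#' @inheritParams csn_statistic
#' @param box_fractions Vector of box fractions (default 0.1, 0.2, 0.3).
#' @param alpha One-sided significance level (default 0.01).
#' @param gene_subset Optional integer vector of gene rows to build the
#'   network on (default all genes).
#' @return List with `adjacency` (symmetric logical matrix over
#'   `gene_subset`, no self-edges), `min_z` (elementwise minimum z over
#'   fractions), `gene_subset`, `box_fractions`, `alpha`.
#' @export
build_network <- function(Xbar, s, box_fractions = c(0.1, 0.2, 0.3),
                          alpha = 0.01, gene_subset = NULL) {
  n <- ncol(Xbar)
  if (n < 10)
    stop("need >= 10 pseudo-cells for the independence statistic; ",
         "use the correlation fallback for small S")
  if (is.null(gene_subset)) gene_subset <- seq_len(nrow(Xbar))
  Xb <- Xbar[gene_subset, , drop = FALSE]
  zmin <- NULL
  for (f in box_fractions) {
    z <- csn_z_matrix(Xb, s, f)
    zmin <- if (is.null(zmin)) z else pmin(zmin, z)
  }
  adj <- zmin > stats::qnorm(1 - alpha)
  diag(adj) <- FALSE
  list(adjacency = adj, min_z = zmin, gene_subset = gene_subset,
       box_fractions = box_fractions, alpha = alpha)
}

#' Gene-gene correlation matrix of a space
#'
#' Pearson correlation between gene rows over the cells of one space.
#' Undefined correlations (zero-variance genes) are set to 0, including
#' the diagonal for such genes.
#'
#' @param Xs Genes x cells submatrix of one space (>= 3 cells advised).
#' @return Genes x genes correlation matrix.
#' @export
gene_correlations <- function(Xs) {
  Xs <- as.matrix(Xs)
  R <- suppressWarnings(stats::cor(t(Xs)))
  R[!is.finite(R)] <- 0
  flat <- apply(Xs, 1, stats::var) == 0
  R[flat, ] <- 0
  R[, flat] <- 0
  R
}

#' Gene-level prediction within a space
#'
#' Each gene is predicted as the |correlation|-weighted average of its
#' network neighbors' expression in the space. Genes with no neighbors or
#' zero total weight fall back to the supplied matrix (normally the
#' cell-level prediction) and are flagged in the fallback mask.
#'
#' @param Xs Genes x cells submatrix of one space.
#' @param network A [build_network()] result (over a gene subset of `Xs`).
#' @param R Correlation matrix from [gene_correlations()] over the same
#'   gene subset.
#' @param fallback Matrix of fallback predictions, same shape as `Xs`.
#' @return List with `G` (same shape as `Xs`) and `fallback_mask`
#'   (logical per gene; `TRUE` where `G` equals the fallback).
#' @export
predict_gene_level <- function(Xs, network, R, fallback = Xs) {
  Xs <- as.matrix(Xs)
  G <- as.matrix(fallback)
  mask <- rep(TRUE, nrow(Xs))
  sub <- network$gene_subset
  W <- network$adjacency * abs(R)
  rs <- rowSums(W)
  ok <- rs > 0
  if (any(ok)) {
    G[sub[ok], ] <- (W[ok, , drop = FALSE] %*%
                       Xs[sub, , drop = FALSE]) / rs[ok]
    mask[sub[ok]] <- FALSE
  }
  dimnames(G) <- dimnames(Xs)
  list(G = G, fallback_mask = mask)
}

#' Gene-level prediction matrix for all spaces
#'
#' Builds the pseudo-cell matrix, then for each space a network centered
#' at that space's pseudo-cell and the per-space correlation matrix, and
#' assembles the full gene-level matrix `G`. For tractability the network
#' is restricted to the `network_genes` most variable genes (all genes if
#' fewer); other genes use the cell-level fallback. With fewer than 10
#' spaces the independence statistic is unreliable, so the edge rule
#' switches to `|Pearson| >= cor_threshold` on pseudo-cells (announced via
#' a message).
#'
#' @param X Genes x cells log-layer matrix (original cell order).
#' @param partition A [partition_cells()] result.
#' @param C Cell-level prediction matrix (fallback), same shape as `X`.
#' @param network_genes Size of the high-variance gene subset (default
#'   2000).
#' @param box_fractions,alpha Passed to [build_network()].
#' @param cor_on Compute per-space correlations over `"cells"` of the
#'   space (default) or over `"pseudocells"`.
#' @param cor_threshold Edge threshold for the small-S fallback (default
#'   0.8).
#' @return List with `G`, `fallback_mask` (genes x spaces logical),
#'   `Xbar`, `gene_subset`.
#' @export
gene_level_matrix <- function(X, partition, C, network_genes = 2000,
                              box_fractions = c(0.1, 0.2, 0.3), alpha = 0.01,
                              cor_on = c("cells", "pseudocells"),
                              cor_threshold = 0.8) {
  cor_on <- match.arg(cor_on)
  X <- as.matrix(X)
  I <- nrow(X)
  Xbar <- build_pseudocells(X, partition)
  S <- partition$S
  vars <- apply(X, 1, stats::var)
  gene_subset <- if (I <= network_genes) seq_len(I)
                 else sort(order(vars, decreasing = TRUE)[seq_len(network_genes)])
  small_S <- S < 10
  if (small_S)
    message("only ", S, " space(s): using the |Pearson| >= ", cor_threshold,
            " pseudo-cell correlation rule instead of the independence test")
  G <- C
  fb <- matrix(TRUE, I, S)
  Rbar <- if (small_S && S >= 3)
    gene_correlations(Xbar[gene_subset, , drop = FALSE]) else NULL
  for (s in seq_len(S)) {
    idx <- partition$blocks[[s]]
    Xs <- X[, idx, drop = FALSE]
    if (small_S) {
      if (is.null(Rbar)) next  # too few pseudo-cells even for correlation
      adj <- abs(Rbar) >= cor_threshold
      diag(adj) <- FALSE
      net <- list(adjacency = adj, gene_subset = gene_subset)
    } else {
      net <- build_network(Xbar, s, box_fractions, alpha, gene_subset)
    }
    Rsub <- if (cor_on == "cells")
      gene_correlations(Xs[gene_subset, , drop = FALSE])
    else if (!is.null(Rbar)) Rbar
    else gene_correlations(Xbar[gene_subset, , drop = FALSE])
    pred <- predict_gene_level(Xs, net, Rsub,
                               fallback = C[, idx, drop = FALSE])
    G[, idx] <- pred$G
    fb[, s] <- pred$fallback_mask
  }
  list(G = G, fallback_mask = fb, Xbar = Xbar, gene_subset = gene_subset)
}
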