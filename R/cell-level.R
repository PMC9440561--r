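#' Pairwise cell distances within a space
#'
#' Euclidean distance between cell columns of the log-layer submatrix,
#' taken over all genes.
#'
#' @param Xs Genes x cells submatrix of one space (>= 2 cells).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
cell_distances <- function(Xs) {
  Xs <- as.matrix(Xs)
  if (ncol(Xs) < 2) stop("a space needs at least 2 cells for distances")
  as.matrix(stats::dist(t(Xs)))
}

#' Adaptive Gaussian kernel weights
#'
#' Row-indexed kernel `k_jj' = exp(-d_jj'^2 / sigma_j^2)` where `sigma_j`
#' is the mean distance from cell `j` to the other cells of its space.
#' Because `sigma` varies by row the matrix is generally not symmetric;
#' the width adapts to the local density of cells. When `sigma_j = 0`
#' (exact duplicate cells) the Gaussian degenerates to the indicator of
#' zero distance.
#'
#' @param D Distance matrix from [cell_distances()].
#' @return Kernel weight matrix, entries in (0, 1], diagonal 1.
#' @export
adaptive_kernel <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sigma <- rowSums(D) / (n - 1)
  K <- matrix(0, n, n, dimnames = dimnames(D))
  for (j in seq_len(n)) {
    K[j, ] <- if (sigma[j] == 0) as.numeric(D[j, ] == 0)
              else exp(-D[j, ]^2 / sigma[j]^2)
  }
  K
}

#' Cell-level prediction within a space
#'
#' Predicts each cell's expression vector as the kernel-weighted average
#' of the other cells in its space; the cell itself is always excluded, so
#' the prediction never depends on the cell's own values.
#'
#' @param Xs Genes x cells submatrix of one space.
#' @param K Kernel weights from [adaptive_kernel()].
#' @return Matrix `Cs` of the same shape as `Xs`.
#' @export
predict_cell_level <- function(Xs, K) {
  Xs <- as.matrix(Xs)
  if (ncol(Xs) < 2) stop("a space needs at least 2 cells for prediction")
  W <- as.matrix(K)
  diag(W) <- 0
  W <- W / rowSums(W)
  Cs <- Xs %*% t(W)
  dimnames(Cs) <- dimnames(Xs)
  Cs
}

#' Cell-level prediction matrix for all spaces
#'
#' Applies [cell_distances()], [adaptive_kernel()] and
#' [predict_cell_level()] to every space of a partition and assembles the
#' full matrix `C`, aligned to the original cell order. A degenerate
#' single-cell space keeps its own values.
#'
#' @param X Genes x cells log-layer matrix (original cell order).
#' @param partition A [partition_cells()] result.
#' @return List with `C` (same shape as `X`) and `sigma` (per-cell kernel
#'   widths, original cell order).
#' @export
cell_level_matrix <- function(X, partition) {
  X <- as.matrix(X)
  C <- X
  sigma <- rep(NA_real_, ncol(X))
  for (idx in partition$blocks) {
    if (length(idx) < 2) next
    Xs <- X[, idx, drop = FALSE]
    D <- cell_distances(Xs)
    K <- adaptive_kernel(D)
    C[, idx] <- predict_cell_level(Xs, K)
    sigma[idx] <- rowSums(D) / (length(idx) - 1)
  }
  list(C = C, sigma = sigma)
}
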