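#' Gini coefficient of an expression vector
#'
#' Mean-difference form `sum_ij |y_i - y_j| / (2 n^2 ybar)`, computed via
#' the equivalent sorted-vector formula. 0 for a constant vector,
#' approaching 1 as the mass concentrates on one entry; scale-invariant.
#'
#' @param values Nonnegative vector, length >= 2, not all zero.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(values) {
  y <- as.numeric(values)
  if (length(y) < 2) stop("need at least 2 values")
  if (any(y < 0)) stop("values must be nonnegative")
  if (all(y == 0)) stop("all-zero vector: Gini undefined")
  n <- length(y)
  ys <- sort(y)
  2 * sum(seq_len(n) * ys) / (n^2 * mean(y)) - (n + 1) / n
}

#' Root mean square error
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  sqrt(mean((y - y_hat)^2))
}

#' Correlation matrix distance
#'
#' `d(R1, R2) = 1 - tr(R1 R2) / (||R1||_F ||R2||_F)`, in `[0, 1]`: 0 for
#' equal (up to scale) correlation structure, 1 for orthogonal structure.
#'
#' @param R1,R2 Symmetric correlation matrices of the same dimension.
#' @return Scalar distance.
#' @export
cmd <- function(R1, R2) {
  R1 <- as.matrix(R1); R2 <- as.matrix(R2)
  if (!all(dim(R1) == dim(R2)) || nrow(R1) != ncol(R1))
    stop("R1 and R2 must be square matrices of the same dimension")
  if (max(abs(R1 - t(R1))) > 1e-8 || max(abs(R2 - t(R2))) > 1e-8)
    stop("correlation matrices must be symmetric")
  n1 <- norm(R1, "F"); n2 <- norm(R2, "F")
  if (n1 == 0 || n2 == 0) stop("zero-norm matrix")
  1 - sum(R1 * R2) / (n1 * n2)
}

label_ranks <- function(labels, levels = NULL) {
  if (is.null(levels)) levels <- if (is.factor(labels)) base::levels(labels)
                                 else sort(unique(labels))
  r <- match(as.character(labels), as.character(levels))
  if (anyNA(r)) stop("labels contain values outside the declared levels")
  r
}

#' Pseudotemporal ordering score
#'
#' Pair-agreement between an inferred cell ordering and ordered reference
#' stage labels: over all cell pairs with *different* labels, a pair
#' scores +1 when the predicted order agrees with the label order and -1
#' when it disagrees; POS is the mean over those pairs. 1 for a perfectly
#' label-ordered permutation, -1 for its exact reversal.
#'
#' @param order Permutation of cell indices (position = predicted rank).
#' @param labels Per-cell reference labels.
#' @param levels Label levels from earliest to latest (default: sorted
#'   unique labels, or factor levels).
#' @return POS in `[-1, 1]`.
#' @export
pos_score <- function(order, labels, levels = NULL) {
  J <- length(labels)
  if (length(order) != J) stop("order and labels length mismatch")
  lr <- label_ranks(labels, levels)
  if (length(unique(lr)) < 2) stop("need at least 2 distinct label levels")
  rank <- base::order(order)  # rank[cell] = predicted position
  dr <- sign(outer(rank, rank, "-"))
  dl <- sign(outer(lr, lr, "-"))
  ut <- upper.tri(dl)
  valid <- dl[ut] != 0
  sum((dr[ut] * dl[ut])[valid]) / sum(valid)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two rankings (e.g. predicted
#' pseudotime rank vs reference stage rank).
#'
#' @param x,y Equal-length numeric or ordered-label vectors.
#' @param levels Optional level ordering applied to both arguments when
#'   they are labels.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y, levels = NULL) {
  if (length(x) != length(y)) stop("length mismatch")
  if (!is.numeric(x)) x <- label_ranks(x, levels)
  if (!is.numeric(y)) y <- label_ranks(y, levels)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("Kendall tau undefined for a constant vector")
  stats::cor(x, y, method = "kendall")
}

#' Pair-counting clustering agreement indices
#'
#' Computes the Adjusted Rand Index, Jaccard index, and Fowlkes-Mallows
#' index from the pair contingency counts of two partitions. Degenerate
#' zero denominators yield 1 for identical partitions and 0 otherwise.
#'
#' @param pred_labels,ref_labels Equal-length label vectors.
#' @return Named list `ari`, `jaccard`, `fm`.
#' @export
clustering_indices <- function(pred_labels, ref_labels) {
  if (length(pred_labels) != length(ref_labels)) stop("length mismatch")
  n <- length(pred_labels)
  tab <- table(pred_labels, ref_labels)
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(tab))
  pairs_pred <- sum(ch2(rowSums(tab)))
  pairs_ref <- sum(ch2(colSums(tab)))
  total <- ch2(n)
  b <- pairs_pred - a
  cc <- pairs_ref - a
  exp_a <- pairs_pred * pairs_ref / total
  den <- (pairs_pred + pairs_ref) / 2 - exp_a
  ari <- if (den == 0) as.numeric(a == pairs_pred && a == pairs_ref)
         else (a - exp_a) / den
  jaccard <- if (a + b + cc == 0) as.numeric(pairs_pred == pairs_ref) # both all-singleton
             else a / (a + b + cc)
  fm <- if (pairs_pred == 0 || pairs_ref == 0)
          as.numeric(pairs_pred == pairs_ref)
        else a / sqrt(pairs_pred * pairs_ref)
  list(ari = ari, jaccard = jaccard, fm = fm)
}

#' Cell-type assignment accuracy
#'
#' Fraction of cells whose assigned label equals the reference label.
#'
#' @param ref_labels,assigned_labels Equal-length label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
acc <- function(ref_labels, assigned_labels) {
  if (length(ref_labels) != length(assigned_labels)) stop("length mismatch")
  mean(as.character(ref_labels) == as.character(assigned_labels))
}
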