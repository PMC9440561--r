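#' Principal-component reduction of cells
#'
#' Computes PCA scores of the cells (cells x genes, centered, unscaled).
#' Component signs are fixed so that each component's largest-magnitude
#' gene loading is positive, making the reduction deterministic.
#'
#' @param m An [expression_matrix()] on the log layer.
#' @param n_components Number of components, `1 <= n <= min(I, J)`.
#' @return A J x n_components score matrix (cells in rows).
#' @export
reduce_dims <- function(m, n_components = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  x <- t(m$values)
  J <- nrow(x); I <- ncol(x)
  if (is.null(n_components)) n_components <- max(2, min(20, J - 1, I - 1))
  if (n_components < 1 || n_components > min(I, J))
    stop("n_components must be in [1, min(I, J)]")
  if (all(apply(x, 2, stats::var) == 0))
    stop("constant matrix: no variance to reduce")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- pr$x[, seq_len(min(n_components, ncol(pr$x))), drop = FALSE]
  rot <- pr$rotation
  for (k in seq_len(ncol(scores))) {
    top <- which.max(abs(rot[, k]))
    if (rot[top, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- m$cell_ids
  scores
}

#' Cluster cells with a Gaussian mixture selected by BIC
#'
#' Fits full-covariance Gaussian mixtures for each number of clusters in
#' `[k_min, min(k_max, J - 1)]` and keeps the BIC-optimal model. With
#' `J <= k_min` every cell becomes its own cluster.
#'
#' @param scores J x d reduced-dimension matrix from [reduce_dims()].
#' @param k_min,k_max Range of cluster counts to consider.
#' @param seed Integer seed (clustering is deterministic given it).
#' @return List with `labels` (integers in `1..k`) and `centers`
#'   (k x d matrix of cluster means in score space).
#' @export
cluster_cells <- function(scores, k_min = 2, k_max = 9, seed = 1) {
  scores <- as.matrix(scores)
  J <- nrow(scores)
  if (J < 2) stop("need at least 2 cells to cluster")
  if (J <= k_min) {
    labels <- seq_len(J)
  } else {
    ks <- k_min:max(k_min, min(k_max, J - 1))
    set.seed(seed)
    fit <- tryCatch(
      mclust::Mclust(scores, G = ks, modelNames = "VVV", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(mclust::Mclust(scores, G = ks, verbose = FALSE),
                      error = function(e) NULL)
    if (is.null(fit)) {
      km <- stats::kmeans(scores, centers = min(3, J - 1), nstart = 10)
      labels <- km$cluster
    } else {
      labels <- as.integer(fit$classification)
    }
  }
  k <- max(labels)
  centers <- t(vapply(seq_len(k), function(g)
    colMeans(scores[labels == g, , drop = FALSE]), numeric(ncol(scores))))
  list(labels = labels, centers = centers)
}

#' Minimum spanning tree over cluster centers
#'
#' Prim's algorithm under Euclidean distance, with distance ties broken by
#' lexicographic edge index so the tree is deterministic.
#'
#' @param centers k x d matrix of cluster-center coordinates.
#' @return Integer matrix with columns `from`, `to` (1-based cluster
#'   indices, `from < to`); `k - 1` rows, empty for a single center.
#' @export
build_mst <- function(centers) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  edges <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (k <= 1) return(edges)
  D <- as.matrix(stats::dist(centers))
  in_tree <- c(TRUE, rep(FALSE, k - 1))
  for (step in seq_len(k - 1)) {
    best <- NULL; best_w <- Inf
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        w <- D[i, j]
        e <- c(min(i, j), max(i, j))
        if (w < best_w ||
            (w == best_w && (e[1] < best[1] ||
                             (e[1] == best[1] && e[2] < best[2])))) {
          best_w <- w; best <- e
        }
      }
    }
    edges <- rbind(edges, best)
    in_tree[best] <- TRUE
  }
  rownames(edges) <- NULL
  edges
}

# All simple paths between two vertices of a tree given its edge list.
tree_path <- function(edges, from, to, k) {
  adj <- vector("list", k)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  # iterative DFS recording parent pointers
  parent <- rep(NA_integer_, k)
  stack <- from; seen <- rep(FALSE, k); seen[from] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; parent[w] <- v; stack <- c(stack, w) }
    }
  }
  if (!seen[to]) stop("tree is not connected")
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}

# Diameter path of the MST: longest by edge count, ties by total Euclidean
# length, then by smallest starting cluster index.
main_path_of <- function(edges, centers) {
  k <- nrow(centers)
  if (k == 1) return(1L)
  D <- as.matrix(stats::dist(centers))
  best <- NULL; best_len <- -1L; best_w <- -Inf
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      p <- tree_path(edges, a, b, k)
      len <- length(p) - 1L
      w <- sum(D[cbind(p[-length(p)], p[-1])])
      if (len > best_len ||
          (len == best_len && w > best_w + 1e-12) ||
          (len == best_len && abs(w - best_w) <= 1e-12 && p[1] < best[1])) {
        best <- p; best_len <- len; best_w <- w
      }
    }
  }
  best
}

# Project points onto the polyline through `centers[path, ]`; returns the
# arc-length position of each point's nearest foot.
project_on_polyline <- function(scores, centers, path) {
  P <- centers[path, , drop = FALSE]
  nseg <- nrow(P) - 1
  J <- nrow(scores)
  if (nseg < 1) return(rep(0, J))
  seg_len <- sqrt(rowSums((P[-1, , drop = FALSE] -
                           P[-nrow(P), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  pos <- rep(0, J); best_d <- rep(Inf, J)
  for (s in seq_len(nseg)) {
    a <- P[s, ]; b <- P[s + 1, ]
    ab <- b - a; ab2 <- sum(ab^2)
    traw <- if (ab2 == 0) rep(0, J)
            else as.vector((sweep(scores, 2, a) %*% ab) / ab2)
    # terminal segments extend beyond their end centers so that cells past
    # the ends of the path get distinct positions instead of piling up at
    # the endpoints
    tlo <- if (s == 1) -Inf else 0
    thi <- if (s == nseg) Inf else 1
    tpar <- pmin(pmax(traw, tlo), thi)
    foot <- outer(tpar, ab) + matrix(a, J, length(a), byrow = TRUE)
    d <- sqrt(rowSums((scores - foot)^2))
    upd <- d < best_d - 1e-12
    pos[upd] <- cum[s] + tpar[upd] * seg_len[s]
    best_d[upd] <- d[upd]
  }
  pos
}

#' Pseudotime ordering of cells
#'
#' Cluster-based minimum-spanning-tree ordering: cells are clustered in PCA
#' space, an MST connects the cluster centers, the tree's diameter path is
#' taken as the main path, and every cell is projected orthogonally onto
#' the polyline through the path's centers. Cells are ranked by arc-length
#' position (ties by cell index); the rank of a cell is its pseudotime.
#' Orientation is fixed by requiring the lowest-index cell of the first
#' path cluster to fall in the earlier half of the ordering.
#'
#' A user-supplied ordering (`config$user_order`, a vector of cell ids)
#' bypasses inference entirely.
#'
#' @param m An [expression_matrix()] on the log layer.
#' @param config Optional list: `n_components`, `k_min`, `k_max`, `seed`,
#'   `user_order`.
#' @return An object of class `PseudotimeResult`: list with `order`
#'   (cell indices, position = pseudotime rank), `cluster_labels`,
#'   `centers`, `mst_edges`, `main_path`, `seed`.
#' @export
order_cells <- function(m, config = list()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  J <- ncol(m$values)
  seed <- config$seed %||% 1L
  if (!is.null(config$user_order)) {
    ord <- match(config$user_order, m$cell_ids)
    if (anyNA(ord) || length(ord) != J || anyDuplicated(ord))
      stop("user_order must be a permutation of the cell ids")
    res <- list(order = ord, cluster_labels = rep(1L, J),
                centers = NULL, mst_edges = NULL, main_path = 1L,
                seed = seed, user_supplied = TRUE)
    class(res) <- "PseudotimeResult"
    return(res)
  }
  scores <- reduce_dims(m, config$n_components)
  cl <- cluster_cells(scores, config$k_min %||% 2, config$k_max %||% 9, seed)
  edges <- build_mst(cl$centers)
  path <- main_path_of(edges, cl$centers)
  pos <- project_on_polyline(scores, cl$centers, path)
  ord <- order(pos, seq_len(J))
  rank <- order(ord)  # rank[cell] = pseudotime position
  first <- which(cl$labels == path[1])
  if (length(first)) {
    anchor <- min(first)
    if (rank[anchor] > ceiling(J / 2)) {
      ord <- rev(ord)
      path <- rev(path)
      rank <- order(ord)
    }
  }
  res <- list(order = ord, cluster_labels = cl$labels, centers = cl$centers,
              mst_edges = edges, main_path = path, seed = seed,
              user_supplied = FALSE)
  class(res) <- "PseudotimeResult"
  res
}

#' @export
print.PseudotimeResult <- function(x, ...) {
  cat("PseudotimeResult: ", length(x$order), " cells, ",
      max(x$cluster_labels), " cluster(s), main path ",
      paste(x$main_path, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Export an ordering as a two-column table
#'
#' @param pt A `PseudotimeResult`.
#' @param cell_ids Cell identifiers in original matrix order.
#' @param path Optional CSV path; if given the table is also written there.
#' @return A data.frame with columns `cell_id`, `rank`.
#' @export
export_order <- function(pt, cell_ids, path = NULL) {
  rank <- order(pt$order)
  tab <- data.frame(cell_id = cell_ids, rank = rank)
  if (!is.null(path))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
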