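pop_sd <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

#' Combine observations with predictions via dropout probabilities
#'
#' The multidimensional blend
#' `x_hat = p * (beta/(alpha+beta) * c + alpha/(alpha+beta) * g) + (1 - p) * x`,
#' where `alpha` and `beta` are the (population) standard deviations of
#' all entries of the cell-level matrix `C` and gene-level matrix `G`
#' respectively: the less dispersed prediction layer gets the larger
#' weight. Entries with `p = 0` are returned unchanged; every imputed
#' entry lies in the interval spanned by `{x, c, g}`. If both layers are
#' constant (`alpha = beta = 0`) the blend uses equal weights.
#'
#' @param X,C,G,P Aligned genes x cells matrices: observations,
#'   cell-level predictions, gene-level predictions, dropout
#'   probabilities.
#' @param per_space Optional [partition_cells()] result; if supplied,
#'   `alpha`/`beta` are computed per space instead of globally.
#' @return List with `X_hat`, `alpha`, `beta` (scalars, or per-space
#'   vectors when `per_space` is given).
#' @export
combine_predictions <- function(X, C, G, P, per_space = NULL) {
  X <- as.matrix(X); C <- as.matrix(C); G <- as.matrix(G); P <- as.matrix(P)
  if (!all(dim(X) == dim(C)) || !all(dim(X) == dim(G)) ||
      !all(dim(X) == dim(P)))
    stop("X, C, G, P must have identical dimensions")
  blend <- function(Xb, Cb, Gb, Pb, a, b) {
    w <- if (a + b == 0) c(0.5, 0.5) else c(b, a) / (a + b)
    Pb * (w[1] * Cb + w[2] * Gb) + (1 - Pb) * Xb
  }
  if (is.null(per_space)) {
    alpha <- pop_sd(C)
    beta <- pop_sd(G)
    X_hat <- blend(X, C, G, P, alpha, beta)
  } else {
    alpha <- beta <- numeric(per_space$S)
    X_hat <- X
    for (s in seq_len(per_space$S)) {
      idx <- per_space$blocks[[s]]
      alpha[s] <- pop_sd(C[, idx])
      beta[s] <- pop_sd(G[, idx])
      X_hat[, idx] <- blend(X[, idx], C[, idx], G[, idx], P[, idx],
                            alpha[s], beta[s])
    }
  }
  dimnames(X_hat) <- dimnames(X)
  list(X_hat = X_hat, alpha = alpha, beta = beta)
}

default_config <- function() {
  list(theta = 1, m = NULL, min_last = 3,
       min_cells_per_gene = 0, min_genes_per_cell = 0,
       network_genes = 2000, box_fractions = c(0.1, 0.2, 0.3),
       network_alpha = 0.01, cor_on = "cells", cor_threshold = 0.8,
       per_space_weights = FALSE,
       n_components = NULL, k_min = 2, k_max = 9,
       user_order = NULL, seed = 1L)
}

#' Run the full imputation pipeline
#'
#' Orchestrates preprocessing (CPM + log2), pseudotime ordering,
#' cell-state space partitioning, cell-level and gene-level prediction,
#' per-space dropout modelling, and the probability-weighted combination.
#' The imputed matrix is returned on the log layer with columns in the
#' *original* input cell order; the run is deterministic given
#' `config$seed`.
#'
#' @param raw An [expression_matrix()] on the counts layer (a cpm or log
#'   layer is accepted and enters the pipeline at the corresponding
#'   stage).
#' @param config Named list overriding defaults: `theta`, `m`,
#'   `min_last`, `min_cells_per_gene`, `min_genes_per_cell`,
#'   `network_genes`, `box_fractions`, `network_alpha`, `cor_on`,
#'   `cor_threshold`, `per_space_weights`, `n_components`, `k_min`,
#'   `k_max`, `user_order`, `seed`.
#' @param verbose Print per-stage progress and timing.
#' @return An object of class `ImputationResult`: list with `imputed`
#'   (log-layer [expression_matrix()]), `alpha`, `beta`, layers `X`, `C`,
#'   `G`, `P`, `fallback_mask`, `pseudotime`, `partition`,
#'   `dropout_fits`, `config`, `version`.
#' @export
run_pipeline <- function(raw, config = list(), verbose = FALSE) {
  stopifnot(inherits(raw, "ExpressionMatrix"))
  cfg <- utils::modifyList(default_config(), config)
  set.seed(cfg$seed)
  say <- function(stage, t0) {
    if (verbose)
      message(sprintf("[%s] %.2fs", stage,
                      as.numeric(proc.time()[3] - t0)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    say(name, t0)
    out
  }
  m_log <- stage("preprocess", {
    m <- filter_matrix(raw, cfg$min_cells_per_gene, cfg$min_genes_per_cell)
    if (m$layer == "counts") m <- normalize_cpm(m)
    if (m$layer == "cpm") m <- log_transform(m, cfg$theta)
    m
  })
  X <- m_log$values
  pt <- stage("pseudotime", order_cells(m_log, cfg))
  partition <- stage("partition", {
    m_cells <- cfg$m %||% compute_m(ncol(X))
    partition_cells(pt$order, m_cells, cfg$min_last)
  })
  cell <- stage("cell_level", cell_level_matrix(X, partition))
  gene <- stage("gene_level",
                gene_level_matrix(X, partition, cell$C,
                                  network_genes = cfg$network_genes,
                                  box_fractions = cfg$box_fractions,
                                  alpha = cfg$network_alpha,
                                  cor_on = cfg$cor_on,
                                  cor_threshold = cfg$cor_threshold))
  drop <- stage("dropout_model", dropout_matrix(X, partition))
  comb <- stage("combine",
                combine_predictions(X, cell$C, gene$G, drop$P,
                                    per_space = if (cfg$per_space_weights)
                                      partition else NULL))
  imputed <- expression_matrix(comb$X_hat, m_log$gene_ids, m_log$cell_ids,
                               layer = "log", theta = cfg$theta)
  res <- list(imputed = imputed, alpha = comb$alpha, beta = comb$beta,
              X = X, C = cell$C, G = gene$G, P = drop$P,
              fallback_mask = gene$fallback_mask,
              pseudotime = pt, partition = partition,
              dropout_fits = drop$fits,
              config = cfg,
              version = as.character(utils::packageVersion("scStateImpute")))
  class(res) <- "ImputationResult"
  res
}

#' @export
print.ImputationResult <- function(x, ...) {
  cat("ImputationResult: ", nrow(x$X), " genes x ", ncol(x$X), " cells, ",
      x$partition$S, " space(s)\n", sep = "")
  cat("  alpha (sd of C) = ", format(x$alpha, digits = 4),
      ", beta (sd of G) = ", format(x$beta, digits = 4), "\n", sep = "")
  invisible(x)
}
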