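# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's own code paths.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Kendall tau-b by explicit pair counting.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# ARI / Jaccard / FM by explicit loop over all pairs of items.
oracle_pair_indices <- function(pred, ref) {
  n <- length(pred)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- pred[i] == pred[j]; sr <- ref[i] == ref[j]
      if (sp && sr) a <- a + 1
      else if (sp && !sr) b <- b + 1
      else if (!sp && sr) cc <- cc + 1
      else d <- d + 1
    }
  }
  tot <- a + b + cc + d
  exp_a <- (a + b) * (a + cc) / tot
  list(ari = (a - exp_a) / ((2 * a + b + cc) / 2 - exp_a),
       jaccard = a / (a + b + cc),
       fm = a / sqrt((a + b) * (a + cc)))
}

# Minimum spanning-tree weight by exhaustive enumeration over Pruefer
# sequences (all n^(n-2) labeled trees); feasible for n <= 6.
oracle_mst_weight <- function(centers) {
  n <- nrow(centers)
  D <- as.matrix(stats::dist(centers))
  if (n == 1) return(0)
  if (n == 2) return(D[1, 2])
  from_pruefer <- function(pr) {
    degree <- rep(1, n)
    for (v in pr) degree[v] <- degree[v] + 1
    edges <- matrix(0, 0, 2)
    avail <- rep(TRUE, n)
    for (v in pr) {
      leaf <- which(degree == 1 & avail)[1]
      edges <- rbind(edges, c(leaf, v))
      degree[leaf] <- 0; avail[leaf] <- FALSE
      degree[v] <- degree[v] - 1
    }
    last <- which(degree == 1 & avail)
    rbind(edges, last)
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- from_pruefer(seqs[r, ])
    best <- min(best, sum(D[e]))
  }
  best
}

# Small random counts matrix wrapped as an ExpressionMatrix.
toy_counts <- function(I = 6, J = 8, seed = 1, zero_frac = 0.3) {
  set.seed(seed)
  v <- matrix(rpois(I * J, 5), I, J)
  v[runif(I * J) < zero_frac] <- 0
  v[1, ] <- v[1, ] + 1  # keep every cell nonempty
  expression_matrix(v)
}
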