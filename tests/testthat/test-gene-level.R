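test_that("pseudo-cells are per-space means (groupby oracle)", {
  X <- rbind(c(2, 4), c(0, 0))
  p <- partition_cells(1:2, 2)
  Xbar <- build_pseudocells(X, p)
  expect_equal(unname(Xbar[, 1]), c(3, 0))

  set.seed(51)
  X2 <- matrix(rnorm(6 * 9), 6, 9)
  ord <- sample(9)
  p2 <- partition_cells(ord, 3)
  Xbar2 <- build_pseudocells(X2, p2)
  for (s in 1:3) {
    expect_equal(unname(Xbar2[, s]),
                 apply(X2[, p2$blocks[[s]], drop = FALSE], 1, mean),
                 tolerance = 1e-12)
  }
})

test_that("scalar and vectorized independence statistics agree", {
  set.seed(52)
  Xbar <- matrix(rnorm(6 * 40), 6, 40)
  for (s in c(1, 17, 40)) {
    for (f in c(0.1, 0.25)) {
      Z <- scStateImpute:::csn_z_matrix(Xbar, s, f)
      for (i in 1:5) for (i2 in (i + 1):6)
        expect_equal(Z[i, i2], csn_statistic(Xbar, s, i, i2, f),
                     tolerance = 1e-12)
    }
  }
})

test_that("independence statistic: degenerate, maximal and null behaviour", {
  set.seed(53)
  Xbar <- rbind(runif(100), runif(100), 7)  # gene 3 constant
  expect_equal(csn_statistic(Xbar, 10, 1, 3, 0.1), 0)
  # identical genes: boxes coincide, z hits its maximum sqrt(n - 1)
  dup <- rbind(Xbar[1, ], Xbar[1, ])
  k <- ceiling(0.1 * 100)
  z_dup <- csn_statistic(dup, 5, 1, 2, 0.1)
  n <- 99
  expect_equal(z_dup, (n * k - k^2) / sqrt(k^2 * (n - k)^2 / (n - 1)))
  expect_gt(z_dup, qnorm(0.99))
  expect_error(csn_statistic(matrix(rnorm(10), 2, 5), 1, 1, 2, 0.1),
               "pseudo-cells")

  # null calibration: approximately standard normal
  set.seed(54)
  zs <- replicate(300, {
    Xb <- matrix(runif(2 * 200), 2, 200)
    csn_statistic(Xb, sample(200, 1), 1, 2, 0.2)
  })
  expect_lt(abs(mean(zs)), 0.15)
  expect_gt(var(zs), 0.7)
  expect_lt(var(zs), 1.3)
})

test_that("network edges: duplicates detected, degenerates excluded, symmetric", {
  set.seed(55)
  x <- runif(100)
  Xbar <- rbind(x, x + 0, rnorm(100), 3)  # pair (1,2) identical; gene 4 flat
  net <- build_network(Xbar, s = 42)
  expect_true(net$adjacency[1, 2])
  expect_false(any(diag(net$adjacency)))
  expect_identical(net$adjacency, t(net$adjacency))
  expect_false(any(net$adjacency[4, ]))
  expect_error(build_network(matrix(rnorm(16), 2, 8), 1), "pseudo-cells")
})

test_that("per-space correlations match a two-pass Pearson oracle", {
  set.seed(56)
  Xs <- matrix(rnorm(4 * 5), 4, 5)
  R <- gene_correlations(Xs)
  for (i in 1:4) for (j in 1:4)
    expect_equal(R[i, j], oracle_pearson(Xs[i, ], Xs[j, ]),
                 tolerance = 1e-12)
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  neg <- rbind(Xs[1, ], -Xs[1, ])
  expect_equal(gene_correlations(neg)[1, 2], -1)
  flat <- rbind(Xs[1, ], 2)
  expect_equal(gene_correlations(flat)[2, ], c(0, 0), ignore_attr = TRUE)
})

test_that("gene-level prediction is the |r|-weighted neighbor average", {
  Xs <- rbind(c(3, 1), c(6, 5), c(0, 2))
  # singleton neighborhood: gene 1 predicted by gene 2 alone
  adj <- matrix(FALSE, 3, 3); adj[1, 2] <- adj[2, 1] <- TRUE
  R <- diag(3); R[1, 2] <- R[2, 1] <- -0.6
  net <- list(adjacency = adj, gene_subset = 1:3)
  pred <- predict_gene_level(Xs, net, R, fallback = Xs * 0)
  expect_equal(unname(pred$G[1, ]), unname(Xs[2, ]))
  expect_false(pred$fallback_mask[1])
  # gene 3 has no neighbors: fallback
  expect_true(pred$fallback_mask[3])
  expect_equal(unname(pred$G[3, ]), c(0, 0))

  # two neighbors with |r| = (1.0, 0.5) and values (3, 6) at a cell -> 4
  adj2 <- matrix(FALSE, 3, 3)
  adj2[3, 1] <- adj2[1, 3] <- adj2[3, 2] <- adj2[2, 3] <- TRUE
  R2 <- diag(3); R2[3, 1] <- R2[1, 3] <- 1; R2[3, 2] <- R2[2, 3] <- -0.5
  net2 <- list(adjacency = adj2, gene_subset = 1:3)
  pred2 <- predict_gene_level(Xs, net2, R2)
  expect_equal(pred2$G[3, 1], (1 * 3 + 0.5 * 6) / 1.5)
  expect_equal(pred2$G[3, 1], 4)
  expect_equal(pred2$G[3, 2], (1 * 1 + 0.5 * 5) / 1.5)
})

test_that("assembled gene-level matrix keeps predictions inside neighbor hulls", {
  set.seed(57)
  d <- simulate_trajectory(60, 120, seed = 57)
  lg <- log_transform(normalize_cpm(
    filter_matrix(expression_matrix(d$observed_counts), 1, 1)))
  X <- lg$values
  p <- partition_cells(seq_len(ncol(X)), 10)
  C <- cell_level_matrix(X, p)$C
  g <- gene_level_matrix(X, p, C)
  expect_identical(dim(g$G), dim(X))
  for (s in seq_len(p$S)) {
    idx <- p$blocks[[s]]
    Xbar_net <- build_network(g$Xbar, s, gene_subset = g$gene_subset)
    nb <- Xbar_net$adjacency
    for (i in which(!g$fallback_mask[, s])[1:3]) {
      if (is.na(i)) break
      neigh <- g$gene_subset[nb[which(g$gene_subset == i), ]]
      if (!length(neigh)) next
      vals <- X[neigh, idx, drop = FALSE]
      expect_true(all(g$G[i, idx] >= apply(vals, 2, min) - 1e-9))
      expect_true(all(g$G[i, idx] <= apply(vals, 2, max) + 1e-9))
    }
  }
})

test_that("few spaces trigger the pseudo-cell correlation fallback rule", {
  set.seed(58)
  X <- matrix(rexp(40 * 30), 40, 30)
  p <- partition_cells(1:30, 10)  # 3 spaces only
  C <- cell_level_matrix(X, p)$C
  expect_message(g <- gene_level_matrix(X, p, C), "Pearson")
  expect_identical(dim(g$G), dim(X))
})
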