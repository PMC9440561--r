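test_that("the blend formula matches hand evaluation and edge cases", {
  # p = 0 keeps the observation
  out <- combine_predictions(matrix(2), matrix(5), matrix(7), matrix(0))
  expect_equal(out$X_hat[1, 1], 2)
  # p = 1 with alpha = beta averages the two predictions
  X <- matrix(c(0, 0), 1); C <- matrix(c(2, -2), 1); G <- matrix(c(4, 0), 1)
  out2 <- combine_predictions(X, C, G, matrix(c(1, 1), 1))
  expect_equal(out2$alpha, out2$beta)
  expect_equal(unname(out2$X_hat[1, ]), c(3, -1))
  expect_error(combine_predictions(matrix(0, 2, 2), matrix(0, 2, 3),
                                   matrix(0, 2, 2), matrix(0, 2, 2)),
               "dimensions")
})

test_that("hand example: p=0.5, x=0, c=2, g=4, alpha=1, beta=3 gives 1.25", {
  # build C and G whose population sds are exactly 1 and 3:
  # entries {c0-1, c0+1} have sd 1; {g0-3, g0+3} have sd 3
  X <- matrix(0, 1, 2)
  C <- matrix(c(2, 4), 1)   # sd = 1, first entry c = 2
  G <- matrix(c(4, 10), 1)  # sd = 3, first entry g = 4
  P <- matrix(c(0.5, 0), 1)
  out <- combine_predictions(X, C, G, P)
  expect_equal(out$alpha, 1)
  expect_equal(out$beta, 3)
  expect_equal(out$X_hat[1, 1], 0.5 * ((3 / 4) * 2 + (1 / 4) * 4))
  expect_equal(out$X_hat[1, 1], 1.25)
})

test_that("imputed entries stay in the hull of {x, c, g} and trust is monotone", {
  set.seed(71)
  n <- 200
  X <- matrix(rnorm(n), 10); C <- matrix(rnorm(n), 10)
  G <- matrix(rnorm(n), 10); P <- matrix(runif(n), 10)
  out <- combine_predictions(X, C, G, P)
  lo <- pmin(X, C, G); hi <- pmax(X, C, G)
  expect_true(all(out$X_hat >= lo - 1e-12 & out$X_hat <= hi + 1e-12))
  # raising p moves x_hat monotonically toward the blended prediction
  blend <- (out$beta * C + out$alpha * G) / (out$alpha + out$beta)
  for (p in c(0, 0.25, 0.5, 0.75, 1)) {
    xh <- combine_predictions(X, C, G, matrix(p, 10, 20))$X_hat
    expect_equal(xh, X + p * (blend - X), tolerance = 1e-12)
  }
})

test_that("pipeline on dropout-free data changes little and stays aligned", {
  set.seed(72)
  d <- simulate_trajectory(100, 80, seed = 72, params = list(dropout = FALSE))
  counts <- d$observed_counts + 1  # strictly positive: no zeros at all
  raw <- expression_matrix(counts)
  res <- suppressMessages(run_pipeline(raw, list(seed = 1)))
  expect_identical(res$imputed$cell_ids, raw$cell_ids)
  expect_identical(res$imputed$gene_ids, raw$gene_ids)
  rel <- abs(res$imputed$values - res$X) / (1 + abs(res$X))
  expect_lt(median(rel), 0.05)
  expect_true(all(res$dropout_fits$fallback))  # no zeros to fit
})

test_that("pipeline output order tracks a user-supplied permutation", {
  set.seed(73)
  d <- simulate_trajectory(80, 50, seed = 73)
  raw <- expression_matrix(d$observed_counts)
  ord_ids <- sample(raw$cell_ids)
  res1 <- suppressMessages(
    run_pipeline(raw, list(seed = 1, user_order = ord_ids)))
  perm <- sample(ncol(raw$values))
  raw2 <- expression_matrix(raw$values[, perm], raw$gene_ids,
                            raw$cell_ids[perm])
  res2 <- suppressMessages(
    run_pipeline(raw2, list(seed = 1, user_order = ord_ids)))
  expect_equal(res2$imputed$values,
               res1$imputed$values[, perm], tolerance = 1e-12)
})

test_that("identical seed and input give bit-identical output", {
  set.seed(74)
  d <- simulate_trajectory(80, 60, seed = 74)
  raw <- expression_matrix(d$observed_counts)
  r1 <- suppressMessages(run_pipeline(raw, list(seed = 7)))
  r2 <- suppressMessages(run_pipeline(raw, list(seed = 7)))
  expect_identical(r1$imputed$values, r2$imputed$values)
  expect_identical(r1$alpha, r2$alpha)
})

test_that("reversing the pseudotime orientation barely moves recovery error", {
  set.seed(75)
  d <- simulate_trajectory(300, 120, seed = 75)
  raw <- expression_matrix(d$observed_counts)
  mk <- mask_entries(raw, 0.2, seed = 76)
  ord_ids <- raw$cell_ids[order(d$true_time)]
  rm_fwd <- suppressMessages(
    run_pipeline(mk$masked, list(seed = 1, user_order = ord_ids)))
  rm_rev <- suppressMessages(
    run_pipeline(mk$masked, list(seed = 1, user_order = rev(ord_ids))))
  mask <- mk$mask[rm_fwd$imputed$gene_ids, rm_fwd$imputed$cell_ids]
  truth <- d$true_log[rm_fwd$imputed$gene_ids, rm_fwd$imputed$cell_ids]
  e_fwd <- rmse(truth[mask], rm_fwd$imputed$values[mask])
  e_rev <- rmse(truth[mask], rm_rev$imputed$values[mask])
  expect_lt(abs(e_fwd - e_rev) / e_fwd, 0.05)
})
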