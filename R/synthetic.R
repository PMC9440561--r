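default_gen_params <- function() {
  list(dispersion = 0.3,            # NB dispersion (size = 1/dispersion)
       a_true = 1.5, b_true = -1,   # logistic dropout on log2(mu + 1)
       profile_weights = c(constant = 0.4, linear = 0.2,
                           sigmoid = 0.2, pulse = 0.2),
       base_meanlog = 0.5, base_sdlog = 1.2,  # lognormal gene base means
       amp_lo = 0.2, amp_hi = 1.8,  # dynamic range of time profiles
       dropout = TRUE)
}

# Per-gene mean profile over latent time t in [0, 1].
profile_fun <- function(type, lo, hi) {
  flip <- stats::runif(1) < 0.5
  span <- hi - lo
  f <- switch(type,
    constant = function(t) rep(1, length(t)),
    linear = function(t) lo + span * t,
    sigmoid = {
      k <- stats::runif(1, 8, 15); t0 <- stats::runif(1, 0.25, 0.75)
      function(t) lo + span / (1 + exp(-k * (t - t0)))
    },
    pulse = {
      t0 <- stats::runif(1, 0.2, 0.8); w <- stats::runif(1, 0.08, 0.2)
      function(t) lo + span * exp(-(t - t0)^2 / (2 * w^2))
    })
  if (flip && type != "constant") function(t) f(1 - t) else f
}

apply_dropout <- function(true_counts, mu, a_true, b_true) {
  p_drop <- 1 - 1 / (1 + exp(a_true + b_true * log2(mu + 1)))
  drop <- matrix(stats::rbinom(length(mu), 1, p_drop) == 1,
                 nrow(mu), ncol(mu), dimnames = dimnames(mu))
  observed <- true_counts
  observed[drop] <- 0
  list(observed = observed, indicator = drop,
       mask = drop & true_counts > 0)
}

finish_dataset <- function(true_counts, mu, gp, extra) {
  if (gp$dropout) {
    dr <- apply_dropout(true_counts, mu, gp$a_true, gp$b_true)
  } else {
    none <- matrix(FALSE, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    dr <- list(observed = true_counts, indicator = none, mask = none)
  }
  lib <- colSums(true_counts)
  lib[lib == 0] <- 1
  true_log <- log2(sweep(true_counts, 2, lib, "/") * 1e6 + 1)
  dimnames(true_log) <- dimnames(true_counts)
  c(list(true_counts = true_counts, true_log = true_log,
         observed_counts = dr$observed, dropout_mask = dr$mask,
         dropout_indicator = dr$indicator, mu = mu,
         gen_params = gp), extra)
}

#' Simulate a single-trajectory scRNA-seq dataset with known truth
#'
#' Cells get latent times `t ~ Uniform(0, 1)`; each gene draws a base mean
#' from a lognormal and a time profile from `{constant, linear, sigmoid,
#' transient pulse}` (mixing weights 0.4/0.2/0.2/0.2); counts are negative
#' binomial around the profile means; dropout then zeroes entries with
#' probability `1 - 1/(1 + exp(a_true + b_true * log2(mu + 1)))` — the
#' same decreasing-logistic mechanism the dropout model fits, so the
#' generator's parameters are recoverable in the noiseless limit.
#'
#' @param n_genes Number of genes (>= 50).
#' @param n_cells Number of cells (>= 30).
#' @param seed Integer seed; the dataset is a deterministic function of
#'   it.
#' @param params Named list overriding [generator defaults]: `dispersion`
#'   (0.3), `a_true` (1.5), `b_true` (-1), `profile_weights`,
#'   `base_meanlog`, `base_sdlog`, `amp_lo`, `amp_hi`, `dropout`
#'   (set `FALSE` to disable dropout).
#' @return A `SyntheticDataset` list: `true_counts`, `true_log`
#'   (log2-CPM of the dropout-free counts), `observed_counts`,
#'   `dropout_mask` (TRUE where a nonzero true count was zeroed),
#'   `dropout_indicator` (the raw dropout draws, including invisible ones
#'   on true zeros), `mu` (latent mean matrix), `true_time`,
#'   `profile_types`, `gen_params`.
#' @export
simulate_trajectory <- function(n_genes, n_cells, seed = 1, params = list()) {
  if (n_genes < 50 || n_cells < 30)
    stop("need n_genes >= 50 and n_cells >= 30")
  gp <- utils::modifyList(default_gen_params(), params)
  set.seed(seed)
  t_cell <- stats::runif(n_cells)
  types <- sample(names(gp$profile_weights), n_genes, replace = TRUE,
                  prob = gp$profile_weights)
  base <- stats::rlnorm(n_genes, gp$base_meanlog, gp$base_sdlog)
  mu <- matrix(0, n_genes, n_cells,
               dimnames = list(paste0("gene", seq_len(n_genes)),
                               paste0("cell", seq_len(n_cells))))
  for (i in seq_len(n_genes)) {
    f <- profile_fun(types[i], gp$amp_lo, gp$amp_hi)
    mu[i, ] <- base[i] * f(t_cell)
  }
  true_counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                       size = 1 / gp$dispersion),
                        n_genes, n_cells, dimnames = dimnames(mu))
  structure(finish_dataset(true_counts, mu, gp,
                           list(true_time = t_cell,
                                profile_types = types)),
            class = "SyntheticDataset")
}

#' Simulate a discrete-group scRNA-seq dataset with known truth
#'
#' Cells are split into `n_groups` (near-)equal groups; a `de_fraction`
#' subset of genes is differentially expressed, shifted up by `2^lfc` in
#' one randomly assigned group. Counts and dropout follow the same
#' negative-binomial + logistic mechanism as [simulate_trajectory()].
#'
#' @param n_genes,n_cells Dataset dimensions.
#' @param n_groups Number of groups (>= 2).
#' @param de_fraction Fraction of genes differentially expressed, in
#'   (0, 1).
#' @param lfc Log2 fold change of DE genes.
#' @param seed Integer seed.
#' @param params As in [simulate_trajectory()].
#' @return A `SyntheticDataset` list as in [simulate_trajectory()] but
#'   with `true_labels` (group per cell) and `de_genes` instead of
#'   `true_time`.
#' @export
simulate_groups <- function(n_genes, n_cells, n_groups = 3,
                            de_fraction = 0.2, lfc = 2, seed = 1,
                            params = list()) {
  if (n_groups < 2) stop("need n_groups >= 2")
  if (de_fraction <= 0 || de_fraction >= 1)
    stop("de_fraction must be in (0, 1)")
  gp <- utils::modifyList(default_gen_params(), params)
  set.seed(seed)
  labels <- sort(rep_len(seq_len(n_groups), n_cells))
  base <- stats::rlnorm(n_genes, gp$base_meanlog, gp$base_sdlog)
  de <- sample(n_genes, round(de_fraction * n_genes))
  de_group <- sample(n_groups, length(de), replace = TRUE)
  mu <- matrix(base, n_genes, n_cells,
               dimnames = list(paste0("gene", seq_len(n_genes)),
                               paste0("cell", seq_len(n_cells))))
  for (k in seq_along(de)) {
    mu[de[k], labels == de_group[k]] <- base[de[k]] * 2^lfc
  }
  true_counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                       size = 1 / gp$dispersion),
                        n_genes, n_cells, dimnames = dimnames(mu))
  structure(finish_dataset(true_counts, mu, gp,
                           list(true_labels = labels, de_genes = de)),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat("SyntheticDataset: ", nrow(x$observed_counts), " genes x ",
      ncol(x$observed_counts), " cells (",
      if (is.null(x$true_time)) "groups" else "trajectory", " mode)\n",
      sep = "")
  invisible(x)
}

#' Mask nonzero entries for recovery benchmarking
#'
#' Sets exactly `round(rate * #nonzero)` uniformly chosen nonzero entries
#' to zero and returns the mask, the standard protocol for measuring how
#' well imputation recovers held-out values.
#'
#' @param m An [expression_matrix()].
#' @param rate Masking rate in (0, 1).
#' @param seed Integer seed.
#' @return List with `masked` (an [expression_matrix()]) and `mask`
#'   (logical matrix, TRUE at masked positions).
#' @export
mask_entries <- function(m, rate, seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (rate <= 0 || rate >= 1) stop("rate must be in (0, 1)")
  nz <- which(m$values > 0)
  if (!length(nz)) stop("no nonzero entries to mask")
  set.seed(seed)
  hit <- sample(nz, round(rate * length(nz)))
  vals <- m$values
  vals[hit] <- 0
  mask <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  mask[hit] <- TRUE
  list(masked = expression_matrix(vals, m$gene_ids, m$cell_ids,
                                  layer = m$layer, theta = m$theta),
       mask = mask)
}
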