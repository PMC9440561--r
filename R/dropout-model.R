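#' Per-gene mean expression and zero fraction within a space
#'
#' @param Xs Genes x cells submatrix of one space (log layer).
#' @return data.frame with columns `mu` (mean over the space's cells,
#'   zeros included) and `zero_frac` (fraction of exactly-zero entries).
#' @export
zero_stats <- function(Xs) {
  Xs <- as.matrix(Xs)
  data.frame(mu = rowMeans(Xs), zero_frac = rowMeans(Xs == 0))
}

clip01 <- function(p, lo = 0.01, hi = 0.99) pmin(pmax(p, lo), hi)

#' Fit a decreasing logistic dropout curve
#'
#' Nonlinear least squares of the zero fraction against mean expression:
#' `z_i ~ 1 - 1/(1 + exp(a + b * mu_i))` with the slope constrained to
#' `b <= 0` (dropout probability decreases with expression). Initialized
#' at `a0 = logit(clip(mean z, 0.01, 0.99))`, `b0 = -1`. On optimizer
#' failure, degenerate input (fewer than 5 distinct `mu` values, or
#' constant `z`), the fallback `(a, b) = (logit(clip(overall zero
#' fraction, 0.01, 0.99)), -1)` is returned with the `fallback` flag set.
#'
#' @param stats data.frame from [zero_stats()] (columns `mu`,
#'   `zero_frac`).
#' @return List with `a`, `b`, `fallback` (logical), `converged`,
#'   `residual_norm`.
#' @export
fit_logistic <- function(stats) {
  mu <- stats$mu
  z <- stats$zero_frac
  keep <- is.finite(mu) & is.finite(z)
  mu <- mu[keep]; z <- z[keep]
  fallback <- function() {
    a <- stats::qlogis(clip01(mean(z)))
    list(a = a, b = -1,
         fallback = TRUE, converged = FALSE,
         residual_norm = sqrt(sum((z - (1 - 1 / (1 + exp(a - mu))))^2)))
  }
  if (length(unique(mu)) < 5 || stats::var(z) == 0) return(fallback())
  a0 <- stats::qlogis(clip01(mean(z)))
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ 1 - 1 / (1 + exp(a + b * mu)),
                      start = list(a = a0, b = -1),
                      lower = c(-Inf, -Inf), upper = c(Inf, 0),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-8, ptol = 1e-8, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  co <- stats::coef(fit)
  if (!all(is.finite(co))) return(fallback())
  list(a = unname(co["a"]), b = unname(min(co["b"], 0)),
       fallback = FALSE, converged = TRUE,
       residual_norm = sqrt(sum(stats::resid(fit)^2)))
}

#' Dropout probabilities for a space
#'
#' Elementwise evaluation of the fitted decreasing logistic curve:
#' `p_ij = 1 - 1/(1 + exp(a + b * x_ij))`, strictly inside (0, 1). With
#' `b <= 0`, `p` is non-increasing in expression, so high expressions keep
#' weight near their observed value.
#'
#' @param Xs Genes x cells submatrix of one space (log layer).
#' @param a,b Fitted logistic parameters.
#' @return Matrix of probabilities, same shape as `Xs`.
#' @export
dropout_probabilities <- function(Xs, a, b) {
  Xs <- as.matrix(Xs)
  P <- 1 - 1 / (1 + exp(a + b * Xs))
  dimnames(P) <- dimnames(Xs)
  P
}

#' Dropout probability matrix for all spaces
#'
#' Fits the logistic curve independently per space and evaluates it on
#' every entry, assembling the full matrix `P` aligned to the original
#' cell order.
#'
#' @param X Genes x cells log-layer matrix (original cell order).
#' @param partition A [partition_cells()] result.
#' @return List with `P` and `fits` (data.frame: space, a, b, fallback,
#'   converged, residual_norm).
#' @export
dropout_matrix <- function(X, partition) {
  X <- as.matrix(X)
  P <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  fits <- vector("list", partition$S)
  for (s in seq_len(partition$S)) {
    idx <- partition$blocks[[s]]
    Xs <- X[, idx, drop = FALSE]
    fit <- fit_logistic(zero_stats(Xs))
    P[, idx] <- dropout_probabilities(Xs, fit$a, fit$b)
    fits[[s]] <- data.frame(space = s, a = fit$a, b = fit$b,
                            fallback = fit$fallback,
                            converged = fit$converged,
                            residual_norm = fit$residual_norm)
  }
  list(P = P, fits = do.call(rbind, fits))
}
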