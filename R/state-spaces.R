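#' Cells per cell-state space
#'
#' The default space size grows slowly with the number of cells:
#' `m = 5 * (ceiling(J / 1000) + 1)`, i.e. 10 cells per space up to 1000
#' cells, 15 up to 2000, and so on.
#'
#' @param J Number of cells (>= 1).
#' @return Integer `m`.
#' @examples
#' compute_m(500)   # 10
#' compute_m(10000) # 55
#' @export
compute_m <- function(J) {
  if (J < 1) stop("J must be >= 1")
  as.integer(5 * (ceiling(J / 1000) + 1))
}

#' Partition pseudotime-ordered cells into consecutive spaces
#'
#' Cuts the ordering into consecutive blocks of `m` cells. A trailing
#' remainder block with fewer than `min_last` cells is merged into the
#' preceding block, so the last space holds between `min_last` and
#' `m + min_last - 1` cells; all other spaces hold exactly `m`.
#'
#' @param order Permutation of cell indices (position = pseudotime rank).
#' @param m Cells per space (>= 2); see [compute_m()].
#' @param min_last Merge threshold for the trailing block (default 3).
#' @return An object of class `StatePartition`: list with `m`, `S`,
#'   `sizes`, `blocks` (list of cell-index vectors in pseudotime order),
#'   `order`, `min_last`.
#' @export
partition_cells <- function(order, m, min_last = 3) {
  J <- length(order)
  if (m < 2) stop("m must be >= 2")
  if (J < m) {
    warning("fewer cells (", J, ") than m (", m, "): using a single space")
    sizes <- J
  } else {
    nfull <- J %/% m
    rem <- J - nfull * m
    sizes <- rep(m, nfull)
    if (rem > 0) {
      if (rem < min_last) sizes[nfull] <- sizes[nfull] + rem
      else sizes <- c(sizes, rem)
    }
  }
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  blocks <- lapply(seq_along(sizes), function(s) order[starts[s]:ends[s]])
  structure(list(m = m, S = length(sizes), sizes = sizes, blocks = blocks,
                 order = order, min_last = min_last),
            class = "StatePartition")
}

#' @export
print.StatePartition <- function(x, ...) {
  cat("StatePartition: ", x$S, " space(s) of sizes ",
      paste(x$sizes, collapse = ", "), " (m=", x$m, ")\n", sep = "")
  invisible(x)
}

#' Export a partition as a table
#'
#' @param partition A `StatePartition`.
#' @param cell_ids Cell identifiers in original matrix order.
#' @param path Optional CSV path.
#' @return data.frame with columns `cell_id`, `rank`, `space_index`.
#' @export
export_partition <- function(partition, cell_ids, path = NULL) {
  ranks <- order(partition$order)
  space <- integer(length(cell_ids))
  for (s in seq_along(partition$blocks)) space[partition$blocks[[s]]] <- s
  tab <- data.frame(cell_id = cell_ids, rank = ranks, space_index = space)
  if (!is.null(path))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  tab
}
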