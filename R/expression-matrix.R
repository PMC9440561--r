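#' Construct an expression matrix
#'
#' The central container of the package: a dense genes x cells matrix of
#' nonnegative values plus gene and cell identifiers and a `layer` tag
#' recording which scale the values live on (`"counts"`, `"cpm"` for
#' counts-per-million, or `"log"` for `log2(cpm + theta)`).
#'
#' @param values Numeric matrix, genes in rows, cells in columns. Must be
#'   finite and nonnegative.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to the rownames of `values` (or `gene1, gene2, ...`).
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column. Defaults to the colnames of `values` (or `cell1, cell2, ...`).
#' @param layer One of `"counts"`, `"cpm"`, `"log"`.
#' @param theta Positive pseudo-count used by the log layer (default 1).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `layer`, `theta`.
#' @examples
#' m <- expression_matrix(matrix(c(1, 0, 0, 3), 2, 2))
#' dim(m$values)
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              layer = c("counts", "cpm", "log"),
                              theta = 1) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene ids: ", paste(utils::head(dup, 3), collapse = ", "))
  dup <- cell_ids[duplicated(cell_ids)]
  if (length(dup)) stop("duplicate cell ids: ", paste(utils::head(dup, 3), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (layer != "log" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative entry at gene '", gene_ids[bad[1]], "', cell '",
         cell_ids[bad[2]], "'")
  }
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("theta must be a positive scalar")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 layer = layer, theta = theta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " cells [layer=", x$layer, ", theta=", x$theta, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

meta_path <- function(path) paste0(path, ".meta")

read_meta <- function(path) {
  mp <- meta_path(path)
  meta <- list(layer = "counts", theta = 1)
  if (file.exists(mp)) {
    for (line in readLines(mp)) {
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) {
        if (kv[1] == "layer") meta$layer <- kv[2]
        if (kv[1] == "theta") meta$theta <- as.numeric(kv[2])
      }
    }
  }
  meta
}

find_sidecar <- function(dir, names) {
  for (nm in names) {
    for (p in file.path(dir, c(nm, paste0(nm, ".gz")))) {
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

#' Read an expression matrix from disk
#'
#' Supports the 10x-style MatrixMarket convention (`matrix.mtx` plus
#' `genes.tsv`/`features.tsv` and `barcodes.tsv` sidecars in the same
#' directory, optionally gzipped) and dense CSV/TSV with gene ids in the
#' first column and cell ids in the header row. If a `<path>.meta` sidecar
#' written by [write_matrix()] is present, the layer tag and theta are
#' restored from it; otherwise the layer is `"counts"`.
#'
#' @param path Path to the `.mtx` or delimited file.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read_meta(path)
  if (format == "mtx") {
    dir <- dirname(path)
    gene_file <- find_sidecar(dir, c("genes.tsv", "features.tsv"))
    barcode_file <- find_sidecar(dir, "barcodes.tsv")
    if (is.null(gene_file))
      stop("missing gene sidecar (genes.tsv or features.tsv) next to ", path)
    if (is.null(barcode_file))
      stop("missing barcodes.tsv sidecar next to ", path)
    vals <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.delim(gene_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(barcode_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(vals))
      stop("gene sidecar has ", length(genes), " entries for ",
           nrow(vals), " matrix rows")
    if (length(cells) != ncol(vals))
      stop("barcode sidecar has ", length(cells), " entries for ",
           ncol(vals), " matrix columns")
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    genes <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    cells <- colnames(vals)
  }
  expression_matrix(vals, genes, cells, layer = meta$layer, theta = meta$theta)
}

#' Write an expression matrix to disk
#'
#' Writes either a dense CSV/TSV (gene ids in the first column) or a
#' MatrixMarket triplet file with `genes.tsv` and `barcodes.tsv` sidecars
#' in the same directory. A `<path>.meta` line records the layer tag and
#' theta so that [read_matrix()] restores them.
#'
#' @param m An [expression_matrix()].
#' @inheritParams read_matrix
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    utils::write.table(data.frame(m$gene_ids, m$gene_ids),
                       file.path(dirname(path), "genes.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(m$cell_ids),
                       file.path(dirname(path), "barcodes.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- data.frame(gene = m$gene_ids, m$values, check.names = FALSE)
    colnames(tab) <- c("gene", m$cell_ids)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  writeLines(c(paste0("layer=", m$layer), paste0("theta=", m$theta)),
             meta_path(path))
  invisible(path)
}

#' Library-size normalization to counts per million
#'
#' Scales every cell so its values sum to one million:
#' `x_ij^N = x_ij^C * 1e6 / sum_k x_kj^C`. Cells with zero total are an
#' error; remove them first with [filter_matrix()].
#'
#' @param m An [expression_matrix()] on the counts layer.
#' @return The matrix on the `"cpm"` layer.
#' @export
normalize_cpm <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer == "log") stop("cannot CPM-normalize a log-layer matrix")
  lib <- colSums(m$values)
  if (any(lib == 0)) {
    stop("all-zero cell column(s): ",
         paste(utils::head(m$cell_ids[lib == 0], 5), collapse = ", "),
         "; remove with filter_matrix() first")
  }
  vals <- sweep(m$values, 2, lib, "/") * 1e6
  expression_matrix(vals, m$gene_ids, m$cell_ids, layer = "cpm",
                    theta = m$theta)
}

#' Log2 transformation with a pseudo-count
#'
#' `x_ij = log2(x_ij^N + theta)`. The pseudo-count prevents infinities at
#' zero; with the default `theta = 1` a zero maps to exactly 0.
#'
#' @param m An [expression_matrix()] on the cpm layer (counts are accepted
#'   for callers that deliberately skip normalization).
#' @param theta Positive pseudo-count.
#' @return The matrix on the `"log"` layer.
#' @export
log_transform <- function(m, theta = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer == "log") stop("matrix is already log-transformed")
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("theta must be a positive scalar")
  expression_matrix(log2(m$values + theta), m$gene_ids, m$cell_ids,
                    layer = "log", theta = theta)
}

#' Invert the log transformation
#'
#' Maps a log-layer matrix back to the cpm scale via `2^x - theta`, clipped
#' at zero (imputation can push `2^x - theta` slightly below zero near the
#' origin). Note the clip means column sums of the result are not forced
#' back to one million.
#'
#' @param m An [expression_matrix()] on the log layer.
#' @param theta Pseudo-count; defaults to the one stored in `m`.
#' @return The matrix on the `"cpm"` layer.
#' @export
inverse_transform <- function(m, theta = m$theta) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "log") stop("inverse_transform expects a log-layer matrix")
  expression_matrix(pmax(2^m$values - theta, 0), m$gene_ids, m$cell_ids,
                    layer = "cpm", theta = theta)
}

#' Filter lowly detected genes and cells
#'
#' Removes genes detected (value > 0) in fewer than `min_cells_per_gene`
#' cells, then cells with fewer than `min_genes_per_cell` detected genes
#' among the surviving genes. Survivor order is preserved. Defaults (0, 0)
#' leave the matrix untouched.
#'
#' @param m An [expression_matrix()].
#' @param min_cells_per_gene,min_genes_per_cell Nonnegative integer
#'   detection thresholds.
#' @return The filtered [expression_matrix()].
#' @export
filter_matrix <- function(m, min_cells_per_gene = 0, min_genes_per_cell = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (min_cells_per_gene < 0 || min_genes_per_cell < 0)
    stop("thresholds must be nonnegative")
  keep_genes <- rowSums(m$values > 0) >= min_cells_per_gene
  if (!any(keep_genes)) stop("filtering removed all genes")
  vals <- m$values[keep_genes, , drop = FALSE]
  keep_cells <- colSums(vals > 0) >= min_genes_per_cell
  if (!any(keep_cells)) stop("filtering removed all cells")
  expression_matrix(vals[, keep_cells, drop = FALSE],
                    m$gene_ids[keep_genes], m$cell_ids[keep_cells],
                    layer = m$layer, theta = m$theta)
}
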