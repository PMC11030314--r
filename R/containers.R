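#' Construct a cells x genes count matrix container
#'
#' The central data container of the package: raw integer UMI counts with
#' cells as rows and genes as columns, plus per-cell metadata (age group,
#' condition, genotype, ...) and optional per-gene flags.
#'
#' @param counts integer matrix or sparse `Matrix` (cells x genes), all
#'   entries nonnegative integers.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing rownames or `cell_1..cell_n`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   existing colnames or `gene_1..gene_m`.
#' @param cell_meta data.frame of per-cell annotations, one row per cell.
#' @param gene_meta data.frame of per-gene annotations, one row per gene.
#' @return An object of class `CountMatrix` with elements `counts`
#'   (a `dgCMatrix`), `cell_ids`, `gene_ids`, `cell_meta`, `gene_meta`.
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                         cell_meta = NULL, gene_meta = NULL) {
  if (is.matrix(counts)) storage.mode(counts) <- "double"
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  vals <- counts@x
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("counts must be finite nonnegative integers")
  n <- nrow(counts); m <- ncol(counts)
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) stop("cell_ids length does not match rows")
  if (length(gene_ids) != m) stop("gene_ids length does not match columns")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (is.null(cell_meta)) cell_meta <- data.frame(row.names = cell_ids)
  if (is.null(gene_meta)) gene_meta <- data.frame(row.names = gene_ids)
  if (nrow(cell_meta) != n) stop("cell_meta rows do not match cell count")
  if (nrow(gene_meta) != m) stop("gene_meta rows do not match gene count")
  rownames(counts) <- cell_ids; colnames(counts) <- gene_ids
  rownames(cell_meta) <- cell_ids; rownames(gene_meta) <- gene_ids
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (ncol(x$cell_meta) > 0)
    cat("  cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a CountMatrix by cells and/or genes
#'
#' @param cm a `CountMatrix`.
#' @param cells,genes logical, integer or character index into cells/genes;
#'   `NULL` keeps all.
#' @return a `CountMatrix` restricted to the requested cells and genes.
#' @export
subset_cells <- function(cm, cells = NULL, genes = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  ci <- if (is.null(cells)) seq_along(cm$cell_ids) else .resolve_idx(cells, cm$cell_ids, "cell")
  gi <- if (is.null(genes)) seq_along(cm$gene_ids) else .resolve_idx(genes, cm$gene_ids, "gene")
  count_matrix(cm$counts[ci, gi, drop = FALSE],
               cell_ids = cm$cell_ids[ci], gene_ids = cm$gene_ids[gi],
               cell_meta = cm$cell_meta[ci, , drop = FALSE],
               gene_meta = cm$gene_meta[gi, , drop = FALSE])
}

.resolve_idx <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop(sprintf("unknown %s id(s): %s", what,
                                 paste(idx[is.na(pos)], collapse = ", ")))
    return(pos)
  }
  if (is.logical(idx)) { stopifnot(length(idx) == length(ids)); return(which(idx)) }
  as.integer(idx)
}

#' Construct a normalized expression matrix
#'
#' Holds log-normalized values together with a record of the normalization
#' applied, so downstream statistics can report their provenance.
#'
#' @param values numeric cells x genes matrix (dense or sparse), finite, >= 0.
#' @param normalization list recording `scale_factor`, `log_base`,
#'   `pseudocount`.
#' @param cell_meta per-cell metadata carried over from the counts.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, normalization = list(), cell_meta = NULL) {
  if (!all(is.finite(values@x %||% values))) stop("values must be finite")
  if (is.null(cell_meta)) cell_meta <- data.frame(row.names = rownames(values))
  structure(list(values = values, normalization = normalization,
                 cell_ids = rownames(values), gene_ids = colnames(values),
                 cell_meta = cell_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a low-dimensional cell embedding
#'
#' @param coords cells x d numeric matrix of coordinates.
#' @param variance_explained numeric vector, proportion of variance captured
#'   by each component (for linear embeddings).
#' @return An `Embedding` object.
#' @export
embedding <- function(coords, variance_explained = NULL) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("embedding coordinates must be finite")
  if (ncol(coords) < 1) stop("embedding must have at least one dimension")
  structure(list(coords = coords, variance_explained = variance_explained,
                 cell_ids = rownames(coords)),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d dims\n", nrow(x$coords), ncol(x$coords)))
  invisible(x)
}
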