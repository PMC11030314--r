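#' Read a count matrix from a 10x-style MTX directory or a CSV file
#'
#' MTX directories follow the 10x triplet layout: `matrix.mtx` in
#' MatrixMarket coordinate format with genes as rows and cells as columns
#' (1-based indices), `features.tsv` (gene ids) and `barcodes.tsv` (cell
#' ids). CSV files hold cells as rows with a header row of gene ids and the
#' cell id in the first column.
#'
#' @param path directory (for `format = "mtx_dir"`) or CSV file path.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param meta optional path to a TSV of per-cell metadata keyed by a
#'   `cell_id` column.
#' @return a [count_matrix()] object. Round-trips bit-exactly with
#'   [write_counts()] for integer matrices.
#' @export
read_counts <- function(path, format = c("mtx_dir", "csv"), meta = NULL) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    feats <- file.path(path, "features.tsv")
    bcs <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feats, bcs))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)          # genes x cells on disk (10x layout)
    gene_ids <- utils::read.table(feats, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    cell_ids <- utils::read.table(bcs, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(gene_ids))
      stop(sprintf("features.tsv has %d entries but matrix has %d rows",
                   length(gene_ids), nrow(m)))
    if (ncol(m) != length(cell_ids))
      stop(sprintf("barcodes.tsv has %d entries but matrix has %d columns",
                   length(cell_ids), ncol(m)))
    cm <- count_matrix(Matrix::t(m), cell_ids = cell_ids, gene_ids = gene_ids)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    cm <- count_matrix(as.matrix(df))
  }
  if (!is.null(meta)) {
    md <- utils::read.table(meta, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!"cell_id" %in% colnames(md)) stop("metadata must have a cell_id column")
    pos <- match(cm$cell_ids, md$cell_id)
    if (anyNA(pos)) stop("metadata missing entries for some cells")
    cm$cell_meta <- cbind(cm$cell_meta,
                          md[pos, setdiff(colnames(md), "cell_id"), drop = FALSE])
    rownames(cm$cell_meta) <- cm$cell_ids
  }
  cm
}

#' Write a count matrix as a 10x-style MTX triplet directory or CSV
#'
#' @param cm a `CountMatrix`.
#' @param path output directory (`mtx_dir`) or CSV file path.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param meta if TRUE and `cm` carries cell metadata, also write
#'   `metadata.tsv` (mtx_dir only).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("mtx_dir", "csv"), meta = TRUE) {
  stopifnot(inherits(cm, "CountMatrix"))
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::t(cm$counts), file.path(path, "matrix.mtx"))
    writeLines(cm$gene_ids, file.path(path, "features.tsv"))
    writeLines(cm$cell_ids, file.path(path, "barcodes.tsv"))
    if (meta && ncol(cm$cell_meta) > 0) {
      md <- cbind(cell_id = cm$cell_ids, cm$cell_meta)
      utils::write.table(md, file.path(path, "metadata.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else {
    m <- as.matrix(cm$counts)
    utils::write.csv(as.data.frame(m), path, quote = FALSE)
  }
  invisible(path)
}
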