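#' Quality-control filter on cells
#'
#' Retains the cells strictly satisfying all three predicates: detected
#' genes > `min_genes`, total counts > `min_counts`, and mitochondrial
#' percentage < `max_mito_pct`. Defaults mirror the filters used for the
#' aging microglia dataset (genes > 1000, counts > 10000, mito < 5). The
#' gene set is unchanged. Mitochondrial genes are flagged either by a
#' logical `mito` column in `gene_meta` or by the mouse "mt-" id prefix.
#'
#' @param cm a `CountMatrix`.
#' @param min_genes,min_counts,max_mito_pct thresholds; strict inequalities.
#' @return the filtered `CountMatrix`, with an attribute `qc_log` recording
#'   how many cells each predicate removed. If no cell passes, a warning is
#'   emitted and an empty (0-cell) matrix returned.
#' @export
qc_filter <- function(cm, min_genes = 1000, min_counts = 10000,
                      max_mito_pct = 5) {
  stopifnot(inherits(cm, "CountMatrix"))
  stats <- per_cell_stats(cm)
  keep <- stats$n_genes > min_genes & stats$total_counts > min_counts &
    stats$pct_mito < max_mito_pct
  log <- c(fail_genes = sum(stats$n_genes <= min_genes),
           fail_counts = sum(stats$total_counts <= min_counts),
           fail_mito = sum(stats$pct_mito >= max_mito_pct),
           removed = sum(!keep), kept = sum(keep))
  if (!any(keep))
    warning("qc_filter: no cells pass the thresholds; returning empty matrix")
  out <- subset_cells(cm, cells = keep)
  attr(out, "qc_log") <- log
  out
}

#' Per-cell QC statistics
#'
#' @param cm a `CountMatrix`.
#' @return data.frame with `n_genes` (genes with count > 0),
#'   `total_counts`, and `pct_mito` per cell.
#' @export
per_cell_stats <- function(cm) {
  counts <- cm$counts
  n_genes <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito <- is_mito_gene(cm)
  mito_counts <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) else 0
  pct <- ifelse(total > 0, 100 * mito_counts / total, 0)
  data.frame(n_genes = n_genes, total_counts = total, pct_mito = pct,
             row.names = cm$cell_ids)
}

is_mito_gene <- function(cm) {
  if ("mito" %in% colnames(cm$gene_meta)) return(as.logical(cm$gene_meta$mito))
  startsWith(tolower(cm$gene_ids), "mt-")
}

#' Gate cells on raw counts of marker genes
#'
#' Conjunction of per-gene raw-count predicates, e.g. the microglia
#' prefilter `Hexb > 4 & Tmem119 > 1 & Cx3cr1 > 4 & Top2a < 1 & Mki67 < 1`.
#'
#' @param cm a `CountMatrix`.
#' @param gates list of gates, each `list(gene=, op=, threshold=)` with
#'   `op` one of `">"`, `"<"`. An empty list is the identity.
#' @return the gated `CountMatrix`.
#' @export
marker_gate <- function(cm, gates = list()) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (length(gates) == 0) return(cm)
  keep <- rep(TRUE, length(cm$cell_ids))
  for (g in gates) {
    if (!all(c("gene", "op", "threshold") %in% names(g)))
      stop("each gate needs gene, op and threshold")
    j <- match(g$gene, cm$gene_ids)
    if (is.na(j)) stop("gated gene not present: ", g$gene)
    x <- as.numeric(cm$counts[, j])
    keep <- keep & switch(g$op,
                          ">" = x > g$threshold,
                          "<" = x < g$threshold,
                          stop("gate op must be '>' or '<'"))
  }
  subset_cells(cm, cells = keep)
}

#' The microglia marker gate used for the Tgfb1 genotype dataset
#' @return a gate list for [marker_gate()].
#' @export
microglia_gates <- function() {
  list(list(gene = "Hexb", op = ">", threshold = 4),
       list(gene = "Tmem119", op = ">", threshold = 1),
       list(gene = "Cx3cr1", op = ">", threshold = 4),
       list(gene = "Top2a", op = "<", threshold = 1),
       list(gene = "Mki67", op = "<", threshold = 1))
}

#' Log-normalize counts
#'
#' Per cell, `value = ln(1 + count / cell_total * scale_factor)`; cells with
#' zero total counts map to all-zero values.
#'
#' @param cm a `CountMatrix`.
#' @param scale_factor library-size scaling constant (default 10000).
#' @return an [expression_matrix()] of normalized values.
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"), scale_factor > 0)
  totals <- Matrix::rowSums(cm$counts)
  sf <- ifelse(totals > 0, scale_factor / totals, 0)
  vals <- methods::as(Matrix::Diagonal(x = sf) %*% cm$counts, "CsparseMatrix")
  vals@x <- log1p(vals@x)
  dimnames(vals) <- dimnames(cm$counts)
  expression_matrix(vals,
                    normalization = list(scale_factor = scale_factor,
                                         log_base = exp(1), pseudocount = 1),
                    cell_meta = cm$cell_meta)
}

#' Select highly variable genes (vst)
#'
#' Ranks genes by their variance of standardized counts after a local
#' polynomial mean-variance trend fit: `log10(variance)` is regressed on
#' `log10(mean)` by loess (span 0.3) over genes with positive variance; raw
#' counts are standardized by the fitted expected standard deviation,
#' clipped at `sqrt(n_cells)`, and the variance of the clipped standardized
#' values is the ranking statistic. Constant genes score 0.
#'
#' @param cm a `CountMatrix`.
#' @param n_top number of genes to return (<= gene count).
#' @param span loess span of the trend fit.
#' @return character vector of the `n_top` top-ranked gene ids, with the
#'   full ranking table in attribute `hvg_table`.
#' @export
select_hvg <- function(cm, n_top = 2500, span = 0.3) {
  stopifnot(inherits(cm, "CountMatrix"))
  m <- ncol(cm$counts)
  if (n_top > m) stop("n_top exceeds the number of genes")
  x <- cm$counts
  n <- nrow(x)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  std_var <- numeric(m)
  usable <- v > 0 & mu > 0
  if (sum(usable) >= 4) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = span,
                        degree = 2)
    exp_sd <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    xs <- as.matrix(x[, usable, drop = FALSE])
    z <- sweep(xs, 2, mu[usable], "-")
    z <- sweep(z, 2, exp_sd, "/")
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[usable] <- apply(z, 2, stats::var)
  } else {
    std_var[usable] <- v[usable]
  }
  ord <- order(-std_var, cm$gene_ids)
  tab <- data.frame(gene = cm$gene_ids[ord], mean = mu[ord],
                    variance = v[ord], standardized_variance = std_var[ord])
  out <- tab$gene[seq_len(n_top)]
  attr(out, "hvg_table") <- tab
  out
}

#' Scale and center expression values per gene
#'
#' Selected genes are centered to mean 0 and scaled to unit variance;
#' zero-variance genes become all-zero columns. Values are clipped at
#' `+/- clip` after scaling.
#'
#' @param em an `ExpressionMatrix`.
#' @param genes gene ids to scale (default: all).
#' @param clip clipping bound for scaled values (default 10).
#' @return dense numeric matrix, cells x selected genes.
#' @export
scale_center <- function(em, genes = NULL, clip = 10) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(genes)) genes <- em$gene_ids
  j <- match(genes, em$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  x <- as.matrix(em$values[, j, drop = FALSE])
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  z <- sweep(x, 2, mu, "-")
  pos <- sd > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sd[pos], "/")
  z[, !pos] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  dimnames(z) <- list(em$cell_ids, genes)
  z
}

#' Principal component analysis of a scaled matrix
#'
#' Components are ordered by decreasing variance explained. Signs are fixed
#' deterministically by forcing the largest-magnitude loading of each
#' component to be positive.
#'
#' @param x cells x genes scaled numeric matrix (from [scale_center()]).
#' @param n_components number of components (<= matrix rank).
#' @return an [embedding()] with `coords` (cells x n_components scores),
#'   `variance_explained`, and the rotation in attribute `rotation`.
#' @export
pca_embed <- function(x, n_components = 25) {
  x <- as.matrix(x)
  r <- min(nrow(x) - 1, ncol(x))
  if (n_components > r)
    stop(sprintf("n_components (%d) exceeds the matrix rank bound (%d)",
                 n_components, r))
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  ve <- (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)]
  rownames(scores) <- rownames(x)
  emb <- embedding(scores, variance_explained = ve)
  attr(emb, "rotation") <- rot
  emb
}
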