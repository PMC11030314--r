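#' Per-gene log2 fold change between two cell groups
#'
#' `log2((mean_a + eps) / (mean_b + eps))` on normalized expression values.
#' Genes whose means are zero in both groups are dropped (their count is
#' reported in attribute `n_dropped`).
#'
#' @param em an `ExpressionMatrix`.
#' @param genes gene ids to score.
#' @param group_a_cells,group_b_cells cell ids (or logical/integer index)
#'   of the contrast groups; both nonempty.
#' @param epsilon pseudocount (default 0.01).
#' @return named numeric vector of log2 fold changes (group A over B).
#' @export
module_log2fc <- function(em, genes, group_a_cells, group_b_cells,
                          epsilon = 0.01) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  ia <- .resolve_idx(group_a_cells, em$cell_ids, "cell")
  ib <- .resolve_idx(group_b_cells, em$cell_ids, "cell")
  if (length(ia) == 0 || length(ib) == 0) stop("both groups must be nonempty")
  j <- match(genes, em$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  ma <- Matrix::colMeans(em$values[ia, j, drop = FALSE])
  mb <- Matrix::colMeans(em$values[ib, j, drop = FALSE])
  keep <- !(ma == 0 & mb == 0)
  if (!any(keep)) stop("all genes have zero means in both groups")
  out <- log2((ma[keep] + epsilon) / (mb[keep] + epsilon))
  names(out) <- genes[keep]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "epsilon") <- epsilon
  out
}

#' One-sample t-test of per-gene log2 fold changes against zero
#'
#' Tests whether a module's genes are shifted as a group: under the null of
#' no change the expected log2 fold change is 0. `t = mean / (sd / sqrt(n))`
#' with a two-sided p from the t distribution on n - 1 degrees of freedom.
#'
#' @param log2fcs numeric vector of per-gene log2 fold changes (>= 2 finite
#'   values).
#' @param module optional module id carried into the result.
#' @return a `ModuleShift` list: `module`, `mean_log2fc`, `t_statistic`,
#'   `p_value`, `n_genes`, `degenerate` (TRUE when the sd is zero, in which
#'   case p is NA).
#' @export
module_shift_test <- function(log2fcs, module = NA) {
  v <- log2fcs[is.finite(log2fcs)]
  if (length(v) < 2) stop("need >= 2 finite log2 fold changes")
  n <- length(v)
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) {
    res <- list(module = module, mean_log2fc = m, t_statistic = if (m == 0) 0 else NA_real_,
                p_value = if (m == 0) 1 else NA_real_, n_genes = n,
                degenerate = TRUE)
  } else {
    t <- m / (s / sqrt(n))
    res <- list(module = module, mean_log2fc = m, t_statistic = t,
                p_value = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE),
                n_genes = n, degenerate = FALSE)
  }
  structure(res, class = "ModuleShift")
}

#' @export
print.ModuleShift <- function(x, ...) {
  cat(sprintf("ModuleShift (module %s): mean log2FC = %.3f, t = %.3f, p = %.3g (n = %d genes)\n",
              as.character(x$module), x$mean_log2fc,
              x$t_statistic %||% NA, x$p_value %||% NA, x$n_genes))
  invisible(x)
}

#' Project a contrast onto gene modules
#'
#' For every module, computes per-gene log2 fold changes between the two
#' cell groups and the one-sample t-test against zero — the metagene
#' summary used to project parabiosis, disease and genotype contrasts onto
#' the aging modules.
#'
#' @param em an `ExpressionMatrix`.
#' @param gm a `GeneModules` (or named list module -> genes).
#' @param group_a_cells,group_b_cells contrast groups (A over B).
#' @param epsilon pseudocount for the fold changes.
#' @return data.frame with one row per module: `module`, `n_genes`,
#'   `mean_log2fc`, `t_statistic`, `p_value`.
#' @export
project_modules <- function(em, gm, group_a_cells, group_b_cells,
                            epsilon = 0.01) {
  mods <- if (inherits(gm, "GeneModules")) gm$modules else gm
  rows <- lapply(names(mods), function(m) {
    genes <- intersect(mods[[m]], em$gene_ids)
    if (length(genes) < 2) return(NULL)
    fc <- module_log2fc(em, genes, group_a_cells, group_b_cells, epsilon)
    sh <- module_shift_test(fc, module = m)
    data.frame(module = m, n_genes = sh$n_genes, mean_log2fc = sh$mean_log2fc,
               t_statistic = sh$t_statistic, p_value = sh$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dotplot statistics: percent expressing and average expression
#'
#' For each (gene, group): the percentage of the group's cells with a
#' positive normalized value, and the mean normalized value over all cells
#' in the group.
#'
#' @param em an `ExpressionMatrix`.
#' @param genes gene ids.
#' @param groups named list: group label -> cell ids (disjoint).
#' @return data.frame with columns `gene`, `group`, `pct_expressing`,
#'   `avg_expression`.
#' @export
dotplot_stats <- function(em, genes, groups) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  j <- match(genes, em$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  rows <- list()
  for (gname in names(groups)) {
    idx <- .resolve_idx(groups[[gname]], em$cell_ids, "cell")
    if (length(idx) == 0) stop("empty group: ", gname)
    sub <- em$values[idx, j, drop = FALSE]
    rows[[gname]] <- data.frame(
      gene = genes, group = gname,
      pct_expressing = 100 * Matrix::colMeans(sub > 0),
      avg_expression = Matrix::colMeans(sub),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin cells into quartiles of an anchor gene's expression
#'
#' Cells are ranked by the anchor's normalized expression (ties broken by
#' cell id) and split into four near-equal bins, Q1 holding the lowest
#' expression and Q4 the highest. Bin sizes differ by at most 1.
#'
#' @param em an `ExpressionMatrix`.
#' @param anchor_gene the ranking gene (e.g. `Tgfb1`).
#' @return named factor of labels Q1..Q4 per cell; attribute `tied` flags
#'   an all-equal anchor.
#' @export
quartile_bins <- function(em, anchor_gene) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  j <- match(anchor_gene, em$gene_ids)
  if (is.na(j)) stop("anchor gene not present: ", anchor_gene)
  n <- length(em$cell_ids)
  if (n < 4) stop("need at least 4 cells to form quartiles")
  x <- as.numeric(em$values[, j])
  ord <- order(x, em$cell_ids)
  qsize <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
  labs <- rep(paste0("Q", 1:4), times = qsize)
  out <- factor(character(n), levels = paste0("Q", 1:4))
  out[ord] <- labs
  names(out) <- em$cell_ids
  attr(out, "tied") <- stats::var(x) == 0
  out
}

#' Quartile-binned co-expression analysis around an anchor gene
#'
#' Cells are quartiled by the anchor's expression; target genes expressed
#' in more than `pct_min` percent of cells are kept; each kept gene's four
#' quartile means are z-scored across quartiles; a Friedman test (genes as
#' blocks, quartiles as treatments) gives the omnibus p, and Dunn's pairwise
#' comparisons of each quartile against Q1 (Holm-corrected) localize the
#' effect. Rising z with quartile indicates expression coupled to the
#' anchor — the autocrine signature when the anchor is the ligand gene.
#'
#' @param em an `ExpressionMatrix`.
#' @param anchor_gene the quartiling gene.
#' @param target_genes genes to score against the anchor.
#' @param pct_min expression-fraction filter in percent (default 25; the
#'   filter is strict, "> 25% of cells").
#' @return a `QuartileResult` list: `anchor`, `quartiles` (per cell),
#'   `tested_genes`, `excluded` (gene -> pct for filtered-out genes),
#'   `z_scores` (genes x quartiles), `friedman_chisq`, `friedman_p`,
#'   `dunn` (data.frame of pairwise comparisons vs Q1).
#' @export
quartile_coexpression <- function(em, anchor_gene, target_genes,
                                  pct_min = 25) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  j <- match(target_genes, em$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ",
                     paste(target_genes[is.na(j)], collapse = ", "))
  q <- quartile_bins(em, anchor_gene)
  x <- as.matrix(em$values[, j, drop = FALSE])
  pct <- 100 * colMeans(x > 0)
  keep <- pct > pct_min
  if (!any(keep)) {
    stop("no target gene expressed in > ", pct_min, "% of cells; per-gene %: ",
         paste(sprintf("%s=%.1f", target_genes, pct), collapse = ", "))
  }
  genes <- target_genes[keep]
  xm <- x[, keep, drop = FALSE]
  qmeans <- t(vapply(seq_along(genes), function(k)
    tapply(xm[, k], q, mean), numeric(4)))
  dimnames(qmeans) <- list(genes, levels(q))
  z <- t(apply(qmeans, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(qmeans)
  fr <- stats::friedman.test(z)
  dunn <- dunn_vs_control(z, control = "Q1")
  structure(list(anchor = anchor_gene, quartiles = q, tested_genes = genes,
                 excluded = stats::setNames(pct[!keep], target_genes[!keep]),
                 z_scores = z, friedman_chisq = unname(fr$statistic),
                 friedman_p = fr$p.value, dunn = dunn),
            class = "QuartileResult")
}

#' Dunn's multiple comparisons against a control column
#'
#' Post-hoc to the Friedman test: within-block (gene) ranks of the
#' treatments (quartiles) are averaged, and each treatment is compared with
#' the control via `z = (Rbar_t - Rbar_c) / sqrt(k (k + 1) / (6 n))` with
#' two-sided normal p-values, Holm-adjusted over the comparisons.
#'
#' @param m blocks x treatments numeric matrix.
#' @param control treatment (column) name serving as the reference.
#' @return data.frame with `comparison`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_vs_control <- function(m, control) {
  stopifnot(control %in% colnames(m))
  rk <- t(apply(m, 1, rank))
  rbar <- colMeans(rk)
  n <- nrow(m); k <- ncol(m)
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(colnames(m), control)
  z <- (rbar[others] - rbar[control]) / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(comparison = paste(others, "vs", control), z = unname(z),
             p_value = unname(p),
             p_adjusted = unname(stats::p.adjust(p, method = "holm")),
             stringsAsFactors = FALSE)
}
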