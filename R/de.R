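#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Non-parametric two-sided Mann-Whitney U test per gene on normalized
#' values, with a normal approximation and tie correction; when both groups
#' have at most 8 cells the p-value is computed by exact enumeration of all
#' group assignments instead. Genes are prefiltered to those expressed in at
#' least `min_pct` percent of cells in at least one group and with
#' |log2FC| >= `min_abs_log2fc`. Q-values are Benjamini-Hochberg across the
#' tested genes. Genes constant across both groups get p = 1.
#'
#' @param em an `ExpressionMatrix`.
#' @param group_a,group_b cell ids (or index) of the two groups, >= 3 cells
#'   each.
#' @param genes genes to consider (default: all).
#' @param min_pct prefilter, percent expressing in at least one group
#'   (default 10).
#' @param min_abs_log2fc prefilter on the absolute log2 fold change
#'   (default 0).
#' @param epsilon pseudocount for the log2 fold change.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation (default FALSE).
#' @return a `DEResult` data.frame: `gene`, `log2fc`, `p_value`, `q_value`,
#'   `pct_a`, `pct_b`.
#' @export
rank_sum_de <- function(em, group_a, group_b, genes = NULL, min_pct = 10,
                        min_abs_log2fc = 0, epsilon = 0.01,
                        continuity = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  ia <- .resolve_idx(group_a, em$cell_ids, "cell")
  ib <- .resolve_idx(group_b, em$cell_ids, "cell")
  if (length(ia) < 3 || length(ib) < 3) stop("both groups need >= 3 cells")
  if (is.null(genes)) genes <- em$gene_ids
  j <- match(genes, em$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  xa <- as.matrix(em$values[ia, j, drop = FALSE])
  xb <- as.matrix(em$values[ib, j, drop = FALSE])
  pct_a <- 100 * colMeans(xa > 0)
  pct_b <- 100 * colMeans(xb > 0)
  ma <- colMeans(xa); mb <- colMeans(xb)
  fc <- log2((ma + epsilon) / (mb + epsilon))
  keep <- (pct_a >= min_pct | pct_b >= min_pct) & abs(fc) >= min_abs_log2fc
  if (!any(keep)) stop("no genes pass the prefilters")
  idx <- which(keep)
  p <- vapply(idx, function(k)
    rank_sum_p(xa[, k], xb[, k], continuity = continuity), numeric(1))
  res <- data.frame(gene = genes[idx], log2fc = fc[idx], p_value = p,
                    q_value = bh_adjust(p), pct_a = pct_a[idx],
                    pct_b = pct_b[idx], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Two-sided Mann-Whitney U p-value for two samples
#'
#' Normal approximation with tie correction; exact enumeration of all
#' `choose(na + nb, na)` assignments when both samples have <= 8 values
#' (two-sided by doubling the smaller tail, capped at 1). Constant combined
#' input returns p = 1.
#'
#' @param a,b numeric vectors.
#' @param continuity apply the 0.5 continuity correction (approximation
#'   mode only).
#' @param exact force or suppress exact enumeration; default `NULL` picks
#'   exact iff both n <= 8.
#' @return two-sided p-value.
#' @export
rank_sum_p <- function(a, b, continuity = FALSE, exact = NULL) {
  na <- length(a); nb <- length(b)
  v <- c(a, b)
  if (stats::var(v) == 0) return(1)
  r <- rank(v)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (is.null(exact)) exact <- na <= 8 && nb <= 8
  if (exact) {
    combos <- utils::combn(na + nb, na)
    Us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    lo <- mean(Us <= U + 1e-9)
    hi <- mean(Us >= U - 1e-9)
    return(min(1, 2 * min(lo, hi)))
  }
  n <- na + nb
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tiecor))
  if (sigma == 0) return(1)
  d <- U - mu
  if (continuity) d <- sign(d) * max(0, abs(d) - 0.5)
  2 * stats::pnorm(abs(d / sigma), lower.tail = FALSE)
}

#' Chi-squared test of overlap between two gene sets
#'
#' Builds the 2x2 contingency table (in A / not in A) x (in B / not in B)
#' over the universe and applies Pearson's chi-squared test (1 df) without
#' continuity correction by default — the test used for the overlap of
#' aging-induced and perturbation-induced gene sets.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe the background gene set (e.g. all tested genes).
#' @param continuity Yates continuity correction (default FALSE).
#' @return an `OverlapResult` list: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `table` (2x2), `chi2`, `p_value`, `expected_overlap`.
#' @export
overlap_chisq <- function(set_a, set_b, universe, continuity = FALSE) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe)) stop("set_a is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set_b is not a subset of the universe")
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)),
               dnn = c("in_a", "in_b"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: one of the sets is empty or spans the universe")
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  d <- abs(tab - e)
  if (continuity) d <- pmax(0, d - 0.5)
  chi2 <- sum(d^2 / e)
  structure(list(n_universe = n, n_a = length(set_a), n_b = length(set_b),
                 n_overlap = sum(in_a & in_b), table = tab, chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 expected_overlap = e[1, 1]),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("Overlap: |A| = %d, |B| = %d, |A n B| = %d of %d (expected %.1f)\n",
              x$n_a, x$n_b, x$n_overlap, x$n_universe, x$expected_overlap))
  cat(sprintf("  chi2 = %.3f, p = %.3g\n", x$chi2, x$p_value))
  invisible(x)
}

#' Restrict two DE results to concordant genes
#'
#' Helper for "concordant overlap" tests: given two `DEResult` tables,
#' returns the gene sets restricted to genes significant in both inputs
#' whose log2 fold changes agree in sign.
#'
#' @param de_a,de_b `DEResult` data.frames.
#' @param q_cutoff significance threshold on the q-values.
#' @return list with `set_a`, `set_b` (both equal to the concordant
#'   intersection joined with each side's own significant genes) and
#'   `concordant` (the sign-agreeing intersection).
#' @export
concordant_sets <- function(de_a, de_b, q_cutoff = 0.05) {
  sig_a <- de_a[de_a$q_value < q_cutoff, ]
  sig_b <- de_b[de_b$q_value < q_cutoff, ]
  common <- intersect(sig_a$gene, sig_b$gene)
  fa <- sig_a$log2fc[match(common, sig_a$gene)]
  fb <- sig_b$log2fc[match(common, sig_b$gene)]
  conc <- common[sign(fa) == sign(fb) & sign(fa) != 0]
  list(set_a = sig_a$gene, set_b = sig_b$gene, concordant = conc)
}
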