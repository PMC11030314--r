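#' Moran's I autocorrelation of a per-cell value on a cell graph
#'
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' where `W = sum_ij w_ij` over the full (symmetric) weight matrix. Applied
#' to a kNN cell graph, a positive I indicates the value is expressed in
#' focal regions of graph space.
#'
#' @param x numeric per-cell values, length `g$n`, non-constant.
#' @param g a `CellGraph`.
#' @return scalar Moran's I.
#' @export
morans_i <- function(x, g) {
  stopifnot(inherits(g, "CellGraph"))
  x <- as.numeric(x)
  if (length(x) != g$n) stop("x length does not match graph size")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("Moran's I is undefined for a constant input")
  num <- as.numeric(z %*% (g$adjacency %*% z))
  (g$n / g$W) * num / ss
}

# Randomization-assumption moments of Moran's I (standard closed forms).
.moran_moments <- function(z, g) {
  n <- g$n
  a <- g$adjacency
  W <- g$W
  S1 <- sum((a + Matrix::t(a))^2) / 2
  S2 <- sum((Matrix::rowSums(a) + Matrix::colSums(a))^2)
  ei <- -1 / (n - 1)
  b2 <- n * sum(z^4) / (sum(z^2)^2)
  num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
    b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)
  den <- (n - 1) * (n - 2) * (n - 3) * W^2
  list(expected = ei, variance = num / den - ei^2)
}

#' Moran's I autocorrelation test over genes
#'
#' Screens genes for focal expression on the cell graph. Three testing
#' modes: `"permutation"` (one-sided Monte Carlo,
#' `p = (1 + #[I_perm >= I_obs]) / (1 + n_perm)`), `"analytic"` (z-score
#' under the randomization-assumption variance, one-sided for positive
#' autocorrelation), and `"exhaustive"` (all n! relabelings; only for tiny
#' graphs, n <= 8). Constant genes get `p = 1` and are flagged. Q-values are
#' Benjamini-Hochberg across the tested genes; the screen used downstream
#' keeps genes with q below `q_cutoff` (0.005 by default).
#'
#' @param em an `ExpressionMatrix`.
#' @param g a `CellGraph` over the same cells.
#' @param genes gene ids to test (default: all).
#' @param method `"permutation"`, `"analytic"` or `"exhaustive"`.
#' @param n_perm permutations for the Monte Carlo mode (>= 99).
#' @param seed RNG seed for the permutations.
#' @return an `AutocorrResult` data.frame with columns `gene`, `I`,
#'   `expected_I` (= -1/(n-1)), `p_value`, `q_value`, `constant`;
#'   attributes `n`, `method`.
#' @export
morans_test <- function(em, g, genes = NULL,
                        method = c("permutation", "analytic", "exhaustive"),
                        n_perm = 999, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(g, "CellGraph"))
  method <- match.arg(method)
  if (is.null(genes)) genes <- em$gene_ids
  if (length(genes) == 0) stop("empty gene list")
  j <- match(genes, em$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  if (method == "permutation" && n_perm < 99) stop("n_perm must be >= 99")
  n <- g$n
  x <- as.matrix(em$values[, j, drop = FALSE])
  if (nrow(x) != n) stop("matrix and graph cell counts differ")
  ei <- -1 / (n - 1)
  a <- g$adjacency
  I_obs <- rep(NA_real_, length(genes))
  p <- rep(NA_real_, length(genes))
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  zc <- sweep(x, 2, colMeans(x))
  ss <- colSums(zc^2)
  ok <- which(!const)
  if (length(ok) > 0) {
    num <- colSums(zc[, ok, drop = FALSE] * as.matrix(a %*% zc[, ok, drop = FALSE]))
    I_obs[ok] <- (n / g$W) * num / ss[ok]
  }
  if (method == "analytic") {
    for (k in ok) {
      mo <- .moran_moments(zc[, k], g)
      p[k] <- stats::pnorm((I_obs[k] - mo$expected) / sqrt(mo$variance),
                           lower.tail = FALSE)
    }
  } else if (method == "exhaustive") {
    if (n > 8) stop("exhaustive mode needs n <= 8")
    perms <- all_permutations(n)
    for (k in ok) {
      z <- zc[, k]
      Ip <- apply(perms, 1, function(pp)
        (n / g$W) * as.numeric(z[pp] %*% (a %*% z[pp])) / ss[k])
      p[k] <- mean(Ip >= I_obs[k] - 1e-12)
    }
  } else {
    p[ok] <- with_seed(seed, {
      vapply(ok, function(k) {
        z <- zc[, k]
        zp <- matrix(z[replicate(n_perm, sample.int(n))], nrow = n)
        Ip <- (n / g$W) * colSums(zp * as.matrix(a %*% zp)) / ss[k]
        (1 + sum(Ip >= I_obs[k] - 1e-12)) / (1 + n_perm)
      }, numeric(1))
    })
  }
  p[const] <- 1
  res <- data.frame(gene = genes, I = I_obs, expected_I = ei, p_value = p,
                    q_value = bh_adjust(p), constant = const,
                    stringsAsFactors = FALSE)
  attr(res, "n") <- n
  attr(res, "method") <- method
  class(res) <- c("AutocorrResult", "data.frame")
  res
}

#' Genes passing the autocorrelation screen
#'
#' @param res an `AutocorrResult` from [morans_test()].
#' @param q_cutoff significance threshold on the BH q-value (default 0.005).
#' @return the significant subset of `res`, ordered by ascending q.
#' @export
significant_genes <- function(res, q_cutoff = 0.005) {
  out <- res[!is.na(res$q_value) & res$q_value < q_cutoff & !res$constant, ]
  out[order(out$q_value, out$gene), ]
}
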