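# Internal helpers shared across modules.

# Run code with a temporarily-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from a global seed; stays below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. Shared by the Moran's I
#' screen and the rank-sum differential expression test.
#'
#' @param p numeric vector of p-values (NA allowed; NAs propagate).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(q)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  q
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted module and branch structure against
#' simulator ground truth. 1 means identical partitions (up to relabeling),
#' ~0 is chance agreement.
#'
#' @param a,b vectors of equal length; any label type.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- ai * bj / choose(n, 2)
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}

# All permutations of 1..n as a matrix (n! rows); used for exhaustive
# permutation tests at tiny n.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- nrow(sub)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * r + 1L):(k * r)
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow = r)
  }
  out
}

# Spearman rank correlation without the cor.test machinery.
spearman <- function(x, y) stats::cor(rank(x), rank(y))
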