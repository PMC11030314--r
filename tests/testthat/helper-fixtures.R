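# Shared fixture builders; everything is generated in code.

# Tiny deterministic count matrix with a mitochondrial gene.
tiny_counts <- function() {
  m <- matrix(c(5, 0, 2, 1,
                0, 3, 0, 0,
                8, 8, 8, 8),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3),
                              c("Hexb", "Tmem119", "mt-Nd1", "Actb")))
  count_matrix(m, cell_meta = data.frame(age = c(6, 12, 24),
                                         row.names = paste0("c", 1:3)))
}

# Random sparse-ish count matrix.
random_counts <- function(n = 30, m = 12, seed = 1, lambda = 3) {
  set.seed(seed)
  x <- matrix(rpois(n * m, lambda), n, m,
              dimnames = list(sprintf("c%03d", 1:n), sprintf("g%03d", 1:m)))
  count_matrix(x)
}

# ExpressionMatrix straight from a dense value matrix.
em_from_values <- function(v) {
  if (is.null(rownames(v))) rownames(v) <- paste0("c", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("g", seq_len(ncol(v)))
  expression_matrix(Matrix::Matrix(v, sparse = TRUE))
}

# CellGraph from a dense adjacency.
graph_from_dense <- function(a) {
  dimnames(a) <- list(paste0("c", seq_len(nrow(a))), paste0("c", seq_len(nrow(a))))
  cell_graph(a)
}

# Random symmetric 0/1 graph guaranteed non-empty.
random_graph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    a <- matrix(rbinom(n * n, 1, p), n, n)
    a <- (a + t(a)) > 0
    diag(a) <- FALSE
    if (sum(a) > 0) break
  }
  graph_from_dense(a * 1)
}

# Independent brute-force Moran's I oracle: explicit double sum.
moran_brute <- function(x, a) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + a[i, j] * z[i] * z[j]
  (n / sum(a)) * num / sum(z^2)
}

# Independent permutation enumerator (distinct implementation from the
# package's): grows permutations by successive insertion.
perms_by_insertion <- function(n) {
  ps <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in ps) for (pos in 0:(k - 1)) {
      nxt[[length(nxt) + 1]] <- append(p, k, after = pos)
    }
    ps <- nxt
  }
  ps
}

# Two-clique graph used for the modularity closed-form check.
two_cliques <- function() {
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1
  diag(a) <- 0
  graph_from_dense(a)
}
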