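#' Group trajectory-significant genes into coregulated modules
#'
#' Each gene's expression is smoothed along pseudotime by binned means
#' (`n_bins` equal-width pseudotime bins; if the trajectory carries branch
#' labels, the last-named branch is profiled in separate bins so genes
#' specific to it are distinguishable from late trunk programs). Pairwise
#' Pearson correlations of the smoothed profiles define a k-nearest-neighbor
#' gene graph (union-symmetrized; edge weight = correlation, non-positive
#' correlations dropped), which is partitioned by Louvain community
#' detection at the given resolution. Modules are numbered by the position
#' of their mean profile's peak along the trajectory, so module 1 peaks
#' earliest (the homeostatic program in the aging data) and the last module
#' is the off-trajectory branch program.
#'
#' @param em an `ExpressionMatrix`.
#' @param traj a `Trajectory` over the same cells.
#' @param sig_genes an `AutocorrResult` (preferred: its q-values rank
#'   module representatives) or a character vector of gene ids.
#' @param resolution Louvain resolution on the gene graph (default 1; see
#'   the methods vignette for why this differs from the cell-graph scale).
#' @param k_gene neighbors per gene in the correlation graph (default 10).
#' @param n_bins pseudotime bins for smoothing (default 20).
#' @param seed Louvain seed.
#' @return a `GeneModules`: list with `assignment` (named integer vector
#'   gene -> module id), `q_values`, `modules` (per-module gene lists ranked
#'   by q), `profiles` (smoothed gene x bin matrix), `resolution`, `seed`,
#'   `single_module` flag.
#' @export
discover_modules <- function(em, traj, sig_genes, resolution = 1,
                             k_gene = 10, n_bins = 20, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(traj, "Trajectory"))
  if (inherits(sig_genes, "AutocorrResult") || is.data.frame(sig_genes)) {
    genes <- sig_genes$gene
    qv <- stats::setNames(sig_genes$q_value, sig_genes$gene)
  } else {
    genes <- as.character(sig_genes)
    qv <- stats::setNames(rep(NA_real_, length(genes)), genes)
  }
  if (length(genes) < 2) stop("need at least 2 significant genes")
  prof <- smooth_along_trajectory(em, traj, genes, n_bins = n_bins)
  cm <- suppressWarnings(stats::cor(t(prof)))
  cm[is.na(cm)] <- 0
  diag(cm) <- -Inf
  ng <- length(genes)
  k <- min(k_gene, ng - 1)
  adj <- matrix(0, ng, ng)
  for (i in seq_len(ng)) {
    nb <- order(-cm[i, ], seq_len(ng))[seq_len(k)]
    w <- pmax(cm[i, nb], 0)
    adj[i, nb] <- pmax(adj[i, nb], w)
    adj[nb, i] <- pmax(adj[nb, i], w)   # union symmetrization
  }
  dimnames(adj) <- list(genes, genes)
  if (all(adj == 0)) {
    assignment <- stats::setNames(rep(1L, ng), genes)
    single <- TRUE
  } else {
    g <- cell_graph(adj)
    part <- louvain_partition(g, resolution = resolution, seed = seed)
    assignment <- part$labels + 1L
    names(assignment) <- genes
    single <- length(unique(assignment)) == 1
  }
  # order module ids by the peak position of the module-mean profile
  mods <- sort(unique(assignment))
  peak <- vapply(mods, function(m) {
    pm <- colMeans(prof[assignment == m, , drop = FALSE])
    which.max(pm)
  }, numeric(1))
  remap <- stats::setNames(order(order(peak, mods)), mods)
  assignment <- stats::setNames(as.integer(remap[as.character(assignment)]),
                                genes)
  module_lists <- lapply(sort(unique(assignment)), function(m) {
    gs <- names(assignment)[assignment == m]
    gs[order(qv[gs], gs)]
  })
  names(module_lists) <- as.character(sort(unique(assignment)))
  structure(list(assignment = assignment, q_values = qv,
                 modules = module_lists, profiles = prof,
                 resolution = resolution, k_gene = k_gene, seed = seed,
                 single_module = single),
            class = "GeneModules")
}

#' Smoothed per-gene expression profiles along a trajectory
#'
#' Binned means over `n_bins` equal-width pseudotime bins. When the
#' trajectory has branch labels, the alphabetically last branch (the
#' smaller, off-trajectory branch by construction of
#' [split_terminal_branches()]) is profiled separately over
#' `ceiling(n_bins / 2)` extra bins appended after the main profile.
#'
#' @param em an `ExpressionMatrix`.
#' @param traj a `Trajectory`.
#' @param genes gene ids to profile.
#' @param n_bins number of main-trajectory bins.
#' @return genes x bins matrix of smoothed expression.
#' @export
smooth_along_trajectory <- function(em, traj, genes, n_bins = 20) {
  j <- match(genes, em$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  x <- as.matrix(em$values[, j, drop = FALSE])
  t <- traj$pseudotime
  br <- traj$branch_labels
  side_labs <- if (is.null(br)) character(0) else setdiff(unique(br), "trunk")
  if (length(side_labs) > 0) {
    side_lab <- max(side_labs)
    main <- br != side_lab
  } else {
    main <- rep(TRUE, length(t))
  }
  # equal-count (quantile) bins: every bin averages ~the same number of
  # cells, so bin noise is uniform and no bin is empty
  bin_means <- function(idx, nb) {
    nb <- min(nb, length(idx))
    b <- ceiling(rank(t[idx], ties.method = "first") / length(idx) * nb)
    out <- matrix(NA_real_, length(genes), nb)
    for (bb in seq_len(nb)) {
      rows <- idx[b == bb]
      out[, bb] <- colMeans(x[rows, , drop = FALSE])
    }
    out
  }
  prof <- bin_means(which(main), n_bins)
  if (!is.null(br) && any(!main)) {
    side <- bin_means(which(!main), ceiling(n_bins / 2))
    prof <- cbind(prof, side)
  }
  rownames(prof) <- genes
  prof
}

#' Top genes per module by significance
#'
#' The `k` genes of each module with the smallest autocorrelation q-value;
#' ties break by gene id. Modules with fewer than `k` genes return all of
#' them. These are the heatmap representatives.
#'
#' @param gm a `GeneModules`.
#' @param k genes per module (default 10).
#' @return named list: module id -> character vector of gene ids.
#' @export
top_module_genes <- function(gm, k = 10) {
  stopifnot(inherits(gm, "GeneModules"))
  lapply(gm$modules, function(gs) gs[seq_len(min(k, length(gs)))])
}

#' @export
print.GeneModules <- function(x, ...) {
  cat(sprintf("GeneModules: %d genes in %d modules (resolution %g)\n",
              length(x$assignment), length(x$modules), x$resolution))
  print(table(x$assignment))
  invisible(x)
}
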