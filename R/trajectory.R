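#' Fit a piecewise-linear principal curve and assign pseudotime
#'
#' An iterative principal-curve fit in embedding space: cells are projected
#' onto the current curve, curve nodes are re-estimated as local averages of
#' the cells projecting near them, and the node sequence is smoothed with a
#' (1/4, 1/2, 1/4) moving average. Iteration stops when the mean squared
#' projection distance changes by less than `tol` or after `max_iter`
#' sweeps. Pseudotime is the normalized arc-length position of each cell's
#' projection, in [0, 1]. The curve is initialized along the first principal
#' axis of the embedding.
#'
#' @param emb an `Embedding` (>= 2 dimensions, >= 10 cells).
#' @param n_segments number of curve segments (default 10; more segments
#'   overfit isotropic noise dimensions at typical dataset sizes).
#' @param max_iter maximum refinement sweeps.
#' @param tol convergence tolerance on the mean squared projection distance.
#' @param seed unused by the deterministic fit; kept for interface stability.
#' @return a `Trajectory`: list with `pseudotime` (named, in [0,1]),
#'   `curve` (ordered node coordinates), `converged`, `objective_trace`
#'   (mean squared projection distance per iteration), `branch_labels`
#'   (NULL until [split_terminal_branches()]), `root_rule`.
#' @export
fit_principal_curve <- function(emb, n_segments = 10, max_iter = 100,
                                tol = 1e-4, seed = NULL) {
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 cells")
  if (ncol(coords) < 2) stop("embedding must have >= 2 dimensions")
  n_nodes <- n_segments + 1

  # init: nodes spread along the first principal axis through the centroid
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2, ctr)
  v <- svd(xc, nu = 0, nv = 1)$v[, 1]
  proj1 <- as.numeric(xc %*% v)
  qs <- seq(min(proj1), max(proj1), length.out = n_nodes)
  nodes <- outer(qs, v) + matrix(ctr, n_nodes, ncol(coords), byrow = TRUE)

  trace <- numeric(0)
  prev_obj <- Inf
  prev_nodes <- nodes
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    pr <- .project_to_polyline(coords, nodes)
    obj <- mean(pr$dist2)
    if (obj > prev_obj) {
      # a refinement that worsens the fit is rejected: keep the previous
      # curve so the objective trace stays non-increasing
      nodes <- prev_nodes
      converged <- TRUE
      break
    }
    trace <- c(trace, obj)
    if (is.finite(prev_obj) && prev_obj - obj < tol) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
    prev_nodes <- nodes
    # re-estimate nodes as local averages over equal arc-length bins
    lam <- pr$lambda
    rng <- range(lam)
    if (diff(rng) == 0) break
    bins <- pmin(n_nodes, 1 + floor((lam - rng[1]) / diff(rng) * n_nodes))
    newnodes <- matrix(NA_real_, n_nodes, ncol(coords))
    for (b in seq_len(n_nodes)) {
      idx <- which(bins == b)
      if (length(idx) > 0) newnodes[b, ] <- colMeans(coords[idx, , drop = FALSE])
    }
    # fill empty bins by linear interpolation along the node index
    for (d in seq_len(ncol(coords)))
      newnodes[, d] <- stats::approx(which(!is.na(newnodes[, d])),
                                     newnodes[!is.na(newnodes[, d]), d],
                                     xout = seq_len(n_nodes), rule = 2)$y
    # smooth the node sequence
    sm <- newnodes
    if (n_nodes >= 3) {
      core <- 2:(n_nodes - 1)
      sm[core, ] <- 0.25 * newnodes[core - 1, , drop = FALSE] +
        0.5 * newnodes[core, , drop = FALSE] +
        0.25 * newnodes[core + 1, , drop = FALSE]
    }
    nodes <- sm
  }
  pr <- .project_to_polyline(coords, nodes)
  lam <- pr$lambda
  t <- if (diff(range(lam)) > 0) (lam - min(lam)) / diff(range(lam)) else
    rep(0, n)
  names(t) <- rownames(coords)
  structure(list(pseudotime = t, curve = nodes, converged = converged,
                 objective_trace = trace, projection_error = pr$dist2,
                 branch_labels = NULL, root_rule = NULL),
            class = "Trajectory")
}

# Project points onto a polyline; returns squared distances and arc-length
# positions lambda.
.project_to_polyline <- function(x, nodes) {
  n <- nrow(x)
  n_seg <- nrow(nodes) - 1
  seglen <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                          nodes[-nrow(nodes), , drop = FALSE])^2))
  cumlen <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, n)
  best_lam <- numeric(n)
  for (s in seq_len(n_seg)) {
    a <- nodes[s, ]; b <- nodes[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      diff <- sweep(x, 2, a)
      d2 <- rowSums(diff^2)
      tt <- rep(0, n)
    } else {
      tt <- pmin(1, pmax(0, (sweep(x, 2, a) %*% ab) / len2))
      proj <- outer(as.numeric(tt), ab) + matrix(a, n, length(a), byrow = TRUE)
      d2 <- rowSums((x - proj)^2)
    }
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lam[upd] <- cumlen[s] + as.numeric(tt)[upd] * sqrt(len2)
  }
  list(dist2 = best_d2, lambda = best_lam)
}

#' Orient a trajectory by designated root cells
#'
#' Flips pseudotime (`t -> 1 - t`) iff the root cells' mean pseudotime
#' exceeds the non-root mean, so that after the call the root (young) cells
#' sit at the low end of the trajectory.
#'
#' @param traj a `Trajectory`.
#' @param root_cells character vector of cell ids anchoring the root.
#' @return the (possibly flipped) `Trajectory`, with `root_rule` recorded.
#' @export
orient_by_root <- function(traj, root_cells) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(root_cells) == 0) stop("root_cells must be nonempty")
  t <- traj$pseudotime
  pos <- match(root_cells, names(t))
  if (anyNA(pos)) stop("root cells absent from trajectory: ",
                       paste(root_cells[is.na(pos)], collapse = ", "))
  root_mean <- mean(t[pos])
  other <- t[-pos]
  flipped <- length(other) > 0 && root_mean > mean(other)
  if (flipped) {
    traj$pseudotime <- 1 - t
    traj$curve <- traj$curve[rev(seq_len(nrow(traj$curve))), , drop = FALSE]
  }
  traj$root_rule <- list(root_cells = root_cells, flipped = flipped)
  traj
}

#' Split the terminal end of a trajectory into branches
#'
#' Cells with pseudotime >= `t_split` are clustered by k-means in embedding
#' space; clusters become branch labels `branch_A`, `branch_B`, ... in
#' decreasing size order, and all earlier cells are labeled `trunk`. This
#' replaces manual selection of terminal graph segments with an explicit,
#' seeded rule.
#'
#' @param traj a `Trajectory`.
#' @param emb the `Embedding` the trajectory was fit on.
#' @param t_split pseudotime split point in (0, 1]; cells at or beyond it
#'   are branch candidates (`t_split = 0` assigns every cell a branch).
#' @param k_branches number of terminal branches (default 2).
#' @param seed k-means seed.
#' @return the `Trajectory` with `branch_labels` filled in; a `degenerate`
#'   attribute flags terminal sets with no real separation (k-means
#'   between-cluster sum of squares ~ 0).
#' @export
split_terminal_branches <- function(traj, emb, t_split = 0.6, k_branches = 2,
                                    seed = 0) {
  stopifnot(inherits(traj, "Trajectory"))
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  if (t_split < 0 || t_split >= 1) stopifnot(t_split == 0)
  t <- traj$pseudotime
  term <- which(t >= t_split)
  if (length(term) < k_branches)
    stop(sprintf("only %d cells beyond t_split, need >= %d",
                 length(term), k_branches))
  km <- with_seed(seed,
                  stats::kmeans(coords[term, , drop = FALSE],
                                centers = k_branches, nstart = 10))
  sizes <- sort(table(km$cluster), decreasing = TRUE)
  lab_map <- stats::setNames(paste0("branch_", LETTERS[seq_len(k_branches)]),
                             names(sizes))
  labels <- rep("trunk", length(t))
  names(labels) <- names(t)
  labels[term] <- lab_map[as.character(km$cluster)]
  traj$branch_labels <- labels
  attr(traj, "degenerate") <- km$betweenss <= 1e-10 * max(km$totss, 1)
  traj
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d cells, %d curve nodes, converged = %s\n",
              length(x$pseudotime), nrow(x$curve), x$converged))
  if (!is.null(x$branch_labels))
    print(table(x$branch_labels))
  invisible(x)
}
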