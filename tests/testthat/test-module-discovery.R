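test_that("morans_i equals the brute-force double sum on exhaustive small cases", {
  set.seed(30)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    g <- random_graph(n, p = 0.5, seed = 30 + rep)
    x <- rnorm(n)
    expect_equal(morans_i(x, g),
                 moran_brute(x, as.matrix(g$adjacency)),
                 tolerance = 1e-12)
  }
})

test_that("morans_i has the textbook sign behavior and degenerate error", {
  # two blocks, within-block edges only, block-indicator values: I = 1
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1; diag(a) <- 0
  g <- graph_from_dense(a)
  expect_equal(morans_i(rep(c(0, 1), each = 3), g), 1, tolerance = 1e-12)
  # alternating values on a chain: all neighbor products negative, I < 0
  chain <- matrix(0, 6, 6)
  for (i in 1:5) { chain[i, i + 1] <- 1; chain[i + 1, i] <- 1 }
  expect_lt(morans_i(rep(c(0, 1), 3), graph_from_dense(chain)), 0)
  expect_error(morans_i(rep(2, 6), g), "constant")
})

test_that("Moran's I is invariant under joint permutation of values and graph", {
  set.seed(31)
  n <- 15
  g <- random_graph(n, seed = 31)
  x <- rnorm(n)
  i0 <- morans_i(x, g)
  for (rep in 1:5) {
    p <- sample(n)
    a <- as.matrix(g$adjacency)[p, p]
    expect_equal(morans_i(x[p], graph_from_dense(a)), i0, tolerance = 1e-12)
  }
})

test_that("morans_i agrees with the ape implementation on regular graphs", {
  # ape row-normalizes the weight matrix; on a k-regular graph that is a
  # uniform rescaling, which Moran's I is invariant to, so the two
  # implementations must agree exactly there
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    a <- matrix(0, n, n)
    for (i in seq_len(n)) {                # cycle: every node has degree 2
      j <- i %% n + 1
      a[i, j] <- 1; a[j, i] <- 1
    }
    g <- graph_from_dense(a)
    x <- rnorm(n)
    ref <- ape::Moran.I(x, a, scaled = FALSE)
    expect_equal(morans_i(x, g), ref$observed, tolerance = 1e-10)
    # complete graph (n-1 regular); ape warns that its analytic sd is
    # degenerate there, which is irrelevant to the observed statistic
    k <- matrix(1, n, n); diag(k) <- 0
    refk <- suppressWarnings(ape::Moran.I(x, k, scaled = FALSE))
    expect_equal(morans_i(x, graph_from_dense(k)), refk$observed,
                 tolerance = 1e-10)
  }
})

test_that("exhaustive permutation p equals independent enumeration at n = 6", {
  set.seed(33)
  g <- random_graph(6, seed = 33)
  x <- rnorm(6)
  em <- em_from_values(matrix(x, 6, 1, dimnames = list(paste0("c", 1:6), "g1")))
  res <- morans_test(em, g, method = "exhaustive")
  # oracle: enumerate all 720 relabelings by successive insertion
  a <- as.matrix(g$adjacency)
  i_obs <- moran_brute(x, a)
  ivals <- vapply(perms_by_insertion(6),
                  function(p) moran_brute(x[p], a), numeric(1))
  expect_equal(res$p_value, mean(ivals >= i_obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$expected_I, -1 / 5)
})

test_that("morans_test flags constant genes and errors on empty input", {
  g <- random_graph(10, seed = 35)
  v <- cbind(g1 = rnorm(10), flat = rep(1, 10))
  rownames(v) <- paste0("c", 1:10)
  em <- em_from_values(v)
  res <- morans_test(em, g, method = "analytic")
  expect_true(res$constant[res$gene == "flat"])
  expect_equal(res$p_value[res$gene == "flat"], 1)
  expect_error(morans_test(em, g, genes = character(0)), "empty")
  expect_error(morans_test(em, g, n_perm = 10, method = "permutation"), "99")
})

test_that("analytic and permutation p-values agree on a smooth signal", {
  set.seed(36)
  n <- 80
  coords <- cbind(seq_len(n) / n, 0.1 * rnorm(n))
  rownames(coords) <- paste0("c", 1:n)
  g <- knn_graph(embedding(coords), 5)
  v <- cbind(smooth = sin(seq_len(n) / n * 2) + rnorm(n, 0, 0.2),
             noise = rnorm(n))
  rownames(v) <- rownames(coords)
  em <- em_from_values(v - min(v))
  pa <- morans_test(em, g, method = "analytic")
  pp <- morans_test(em, g, method = "permutation", n_perm = 999, seed = 4)
  expect_lt(pa$p_value[1], 0.001)
  expect_lt(pp$p_value[1], 0.01)
  expect_gt(pa$p_value[2], 0.05)
  expect_gt(pp$p_value[2], 0.05)
})

test_that("bh_adjust matches the step-up definition and p.adjust", {
  set.seed(37)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    # direct definition: q_(i) = min_{j >= i} p_(j) m / j
    m <- length(p)
    o <- order(p)
    direct <- numeric(m)
    for (i in seq_len(m))
      direct[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    expect_equal(q, direct, tolerance = 1e-12)
  }
  expect_true(all(is.na(bh_adjust(c(NA, NA)))))
  # q is monotone non-decreasing in p
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("planted genes pass the q < 0.005 screen and background genes do not", {
  ds <- simulate_aging_dataset(sim_config(seed = 2))
  em <- lognormalize(ds$counts)
  emb <- pca_embed(scale_center(em, select_hvg(ds$counts, 60)), 3)
  g <- knn_graph(emb, 15)
  res <- morans_test(em, g, method = "analytic")
  mod <- ds$truth$genes$module[match(res$gene, ds$truth$genes$gene)]
  planted <- mod != "background"
  expect_true(all(res$q_value[planted] < 0.005))
  expect_gt(mean(res$q_value[!planted] >= 0.005), 0.9)
})

test_that("discover_modules separates anti-correlated groups and respects resolution", {
  set.seed(38)
  n <- 300
  t <- sort(runif(n))
  up <- outer(t, rep(1, 4)) + matrix(rnorm(n * 4, 0, 0.05), n)
  down <- outer(1 - t, rep(1, 4)) + matrix(rnorm(n * 4, 0, 0.05), n)
  v <- cbind(up, down)
  colnames(v) <- c(paste0("up", 1:4), paste0("down", 1:4))
  rownames(v) <- paste0("c", 1:n)
  em <- em_from_values(v - min(v))
  traj <- structure(list(pseudotime = stats::setNames(t, rownames(v)),
                         curve = cbind(0:1, c(0, 0)), converged = TRUE,
                         objective_trace = 0, branch_labels = NULL,
                         root_rule = NULL),
                    class = "Trajectory")
  gm <- discover_modules(em, traj, colnames(v), resolution = 1, k_gene = 3)
  truth <- rep(1:2, each = 4)
  expect_equal(adjusted_rand_index(gm$assignment, truth), 1)
  # anti-correlated groups share no positive-correlation edges, so they can
  # never merge, at any resolution
  gm0 <- discover_modules(em, traj, colnames(v), resolution = 1e-9, k_gene = 3)
  expect_equal(length(gm0$modules), 2)
  # on a connected gene graph (two positively correlated ramp groups and a
  # neighbor count forcing cross-group edges), resolution -> 0 merges
  # everything into one module while resolution 1 keeps the groups apart
  set.seed(39)
  early <- sapply(1:4, function(i) 1 / (1 + exp(-12 * (t - 0.3))) +
                    rnorm(n, 0, 0.05))
  late <- sapply(1:4, function(i) 1 / (1 + exp(-12 * (t - 0.7))) +
                   rnorm(n, 0, 0.05))
  vc <- cbind(early, late)
  colnames(vc) <- c(paste0("early", 1:4), paste0("late", 1:4))
  rownames(vc) <- paste0("c", 1:n)
  emc <- em_from_values(vc - min(vc))
  gmc0 <- discover_modules(emc, traj, colnames(vc), resolution = 1e-9,
                           k_gene = 5)
  expect_equal(length(gmc0$modules), 1)
  expect_true(gmc0$single_module)
  gmc1 <- discover_modules(emc, traj, colnames(vc), resolution = 1,
                           k_gene = 5)
  expect_equal(adjusted_rand_index(gmc1$assignment, rep(1:2, each = 4)), 1)
  expect_error(discover_modules(em, traj, "up1"), "at least 2")
})

test_that("module recovery degrades gracefully with increasing noise", {
  # ARI averaged over seeds is non-increasing along a 3-point dispersion grid
  ari_at <- function(size, seeds) {
    mean(vapply(seeds, function(s) {
      ds <- simulate_aging_dataset(sim_config(n_cells_per_age = 250,
                                              nb_dispersion = size, seed = s))
      em <- lognormalize(ds$counts)
      emb <- pca_embed(scale_center(em, select_hvg(ds$counts, 60)), 3)
      traj <- orient_by_root(fit_principal_curve(emb),
                             ds$counts$cell_ids[ds$counts$cell_meta$age == 6])
      traj <- split_terminal_branches(traj, emb)
      sig <- significant_genes(morans_test(em, knn_graph(emb, 15),
                                           method = "analytic"))
      gm <- discover_modules(em, traj, sig)
      truth <- ds$truth$genes$module[match(names(gm$assignment),
                                           ds$truth$genes$gene)]
      adjusted_rand_index(gm$assignment, truth)
    }, numeric(1)))
  }
  seeds <- c(1, 2)
  aris <- c(ari_at(2, seeds), ari_at(0.3, seeds), ari_at(0.05, seeds))
  tol <- 0.1   # one seed-average of slack
  expect_true(all(diff(aris) <= tol))
  expect_gte(aris[1], 0.8)
})

test_that("top_module_genes ranks by q with alphabetical ties", {
  qv <- c(a = 0.3, b = 0.1, c = 0.1, d = 0.2, e = NA)
  gm <- structure(list(assignment = stats::setNames(c(1, 1, 1, 1, 2),
                                                    names(qv)),
                       q_values = qv,
                       modules = list("1" = c("b", "c", "d", "a"), "2" = "e"),
                       resolution = 1, seed = 0, single_module = FALSE),
                  class = "GeneModules")
  top <- top_module_genes(gm, k = 2)
  expect_equal(top[["1"]], c("b", "c"))   # q ties broken alphabetically
  expect_equal(top[["2"]], "e")           # short module returns all genes
  top10 <- top_module_genes(gm, k = 10)
  expect_equal(top10[["1"]], c("b", "c", "d", "a"))
  # agreement with a direct sort on a random table
  set.seed(39)
  genes <- paste0("g", 1:30)
  q <- round(runif(30), 2)
  assign <- sample(1:3, 30, replace = TRUE)
  mods <- lapply(split(genes, assign), function(gs) gs[order(q[match(gs, genes)], gs)])
  gm2 <- structure(list(assignment = stats::setNames(assign, genes),
                        q_values = stats::setNames(q, genes), modules = mods,
                        resolution = 1, seed = 0, single_module = FALSE),
                   class = "GeneModules")
  top5 <- top_module_genes(gm2, 5)
  for (m in names(mods)) {
    gs <- split(genes, assign)[[m]]
    want <- gs[order(q[match(gs, genes)], gs)][seq_len(min(5, length(gs)))]
    expect_equal(top5[[m]], want)
  }
})
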