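test_that("module_log2fc matches the closed form and is antisymmetric", {
  set.seed(40)
  v <- matrix(rexp(40 * 6), 40, 6)
  colnames(v) <- paste0("g", 1:6)
  em <- em_from_values(v)
  a <- paste0("c", 1:20); b <- paste0("c", 21:40)
  eps <- 0.01
  fc <- module_log2fc(em, colnames(v), a, b, epsilon = eps)
  want <- log2((colMeans(v[1:20, ]) + eps) / (colMeans(v[21:40, ]) + eps))
  expect_equal(unname(fc), unname(want), tolerance = 1e-12,
               ignore_attr = TRUE)
  # swapping the groups negates every value exactly
  rev <- module_log2fc(em, colnames(v), b, a, epsilon = eps)
  expect_equal(unname(rev), -unname(fc), tolerance = 1e-12)
  # identical groups: all zero
  same <- module_log2fc(em, colnames(v), a, a)
  expect_true(all(same == 0))
  # mean_a = 2 mean_b with a tiny pseudocount: log2FC ~ 1
  v2 <- cbind(g1 = c(rep(4, 10), rep(2, 10)))
  em2 <- em_from_values(v2)
  fc2 <- module_log2fc(em2, "g1", paste0("c", 1:10), paste0("c", 11:20),
                       epsilon = 1e-9)
  expect_equal(unname(fc2), 1, tolerance = 1e-6, ignore_attr = TRUE)
  # genes with both means zero are dropped and counted
  v3 <- cbind(g1 = rep(0, 4), g2 = c(1, 2, 3, 4))
  fc3 <- module_log2fc(em_from_values(v3), c("g1", "g2"),
                       c("c1", "c2"), c("c3", "c4"))
  expect_equal(names(fc3), "g2")
  expect_equal(attr(fc3, "n_dropped"), 1)
  expect_error(module_log2fc(em_from_values(v3), "g1",
                             c("c1", "c2"), c("c3", "c4")),
               "zero means")
})

test_that("module_shift_test reproduces the textbook one-sample t", {
  x <- c(0.5, 1.0, 1.5, 2.0)
  res <- module_shift_test(x)
  # oracle: t = mean / (sd / sqrt(n)), p from the t CDF with n - 1 df
  t_want <- mean(x) / (sd(x) / 2)
  expect_equal(res$t_statistic, t_want, tolerance = 1e-12)
  expect_equal(res$t_statistic, 3.872983, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(t_want, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.0305, tolerance = 5e-3)
  expect_equal(res$mean_log2fc, 1.25)
  # agreement with stats::t.test across random vectors
  set.seed(41)
  for (rep in 1:10) {
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    ours <- module_shift_test(y)
    ref <- t.test(y, mu = 0)
    expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("module_shift_test handles degenerate inputs per contract", {
  z <- module_shift_test(rep(0, 5))
  expect_equal(z$t_statistic, 0)
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  const <- module_shift_test(rep(0.7, 5))
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))
  expect_error(module_shift_test(1.5), "finite")
  # t is invariant under scaling all values by a positive constant
  set.seed(42)
  y <- rnorm(12, 0.4)
  expect_equal(module_shift_test(y)$t_statistic,
               module_shift_test(3.7 * y)$t_statistic, tolerance = 1e-12)
})

test_that("the shift test has the expected power at the planted effect size", {
  # delta = 0.5 shift, per-gene sd 0.2, 30 genes: rejects in >= 95% of runs
  set.seed(43)
  rejected <- vapply(1:200, function(i) {
    module_shift_test(rnorm(30, 0.5, 0.2))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("dotplot_stats equals a direct per-group loop", {
  set.seed(44)
  v <- matrix(rpois(60 * 5, 1.2), 60, 5)
  dimnames(v) <- list(paste0("c", 1:60), paste0("g", 1:5))
  em <- em_from_values(v)
  groups <- list(young = paste0("c", 1:30), old = paste0("c", 31:60))
  st <- dotplot_stats(em, colnames(v), groups)
  for (g in colnames(v)) for (gr in names(groups)) {
    rows <- match(groups[[gr]], rownames(v))
    row <- st[st$gene == g & st$group == gr, ]
    expect_equal(row$pct_expressing, 100 * mean(v[rows, g] > 0))
    expect_equal(row$avg_expression, mean(v[rows, g]))
  }
  # all-zero gene: pct 0 and avg 0 everywhere; all-positive: pct 100
  v2 <- cbind(zero = rep(0, 10), allpos = rep(2, 10))
  st2 <- dotplot_stats(em_from_values(v2), c("zero", "allpos"),
                       list(all = paste0("c", 1:10)))
  expect_equal(st2$pct_expressing, c(0, 100))
  expect_equal(st2$avg_expression, c(0, 2))
  # pct is invariant to the normalization scale factor
  cm <- random_counts(40, 6, seed = 9)
  p1 <- dotplot_stats(lognormalize(cm, 1e4), cm$gene_ids,
                      list(all = cm$cell_ids))$pct_expressing
  p2 <- dotplot_stats(lognormalize(cm, 500), cm$gene_ids,
                      list(all = cm$cell_ids))$pct_expressing
  expect_equal(p1, p2)
  expect_error(dotplot_stats(em, "g1", list(bad = character(0))), "bad")
})

test_that("quartile_bins slices ranked cells into near-equal quartiles", {
  v <- cbind(anchor = c(8, 1, 5, 3, 7, 2, 6, 4))
  rownames(v) <- paste0("c", 1:8)
  em <- em_from_values(v)
  q <- quartile_bins(em, "anchor")
  expect_equal(as.integer(table(q)), rep(2L, 4))
  # brute-force: sort and slice
  ord <- order(v[, 1], rownames(v))
  want <- character(8)
  want[ord] <- rep(paste0("Q", 1:4), each = 2)
  expect_equal(as.character(q), want)
  expect_equal(as.character(q[c("c2", "c6")]), c("Q1", "Q1"))
  expect_equal(as.character(q["c1"]), "Q4")
  # near-equal sizes when n is not divisible by 4
  v2 <- cbind(anchor = rnorm(10)); rownames(v2) <- paste0("c", 1:10)
  q2 <- quartile_bins(em_from_values(v2 - min(v2)), "anchor")
  expect_lte(diff(range(table(q2))), 1)
  # all-equal anchor still bins near-equally, flagged
  v3 <- cbind(anchor = rep(1, 8)); rownames(v3) <- paste0("c", 1:8)
  q3 <- quartile_bins(em_from_values(v3), "anchor")
  expect_lte(diff(range(table(q3))), 1)
  expect_true(attr(q3, "tied"))
  expect_error(quartile_bins(em_from_values(cbind(a = 1:3)), "a"), "4 cells")
})

test_that("quartile_coexpression finds planted anchor-coupled genes", {
  set.seed(45)
  n <- 400
  anchor <- rexp(n)
  coupled <- sapply(1:5, function(i) anchor * 0.8 + rexp(n) * 0.3)
  indep <- matrix(rexp(n * 3), n, 3)
  rare <- ifelse(runif(n) < 0.1, 1, 0)   # expressed in ~10% of cells
  v <- cbind(anchor, coupled, indep, rare)
  colnames(v) <- c("Tgfb1", paste0("target", 1:5), paste0("indep", 1:3), "rare")
  rownames(v) <- paste0("c", 1:n)
  em <- em_from_values(v)
  res <- quartile_coexpression(em, "Tgfb1",
                               c(paste0("target", 1:5), "rare"), pct_min = 25)
  # the >25% expression filter excludes the rare gene
  expect_false("rare" %in% res$tested_genes)
  expect_true("rare" %in% names(res$excluded))
  # coupled targets rise from Q1 to Q4 and the omnibus test fires
  expect_true(all(res$z_scores[, "Q4"] > res$z_scores[, "Q1"]))
  expect_lt(res$friedman_p, 0.05)
  q4row <- res$dunn[res$dunn$comparison == "Q4 vs Q1", ]
  expect_lt(q4row$p_adjusted, 0.05)
  expect_error(quartile_coexpression(em, "Tgfb1", "rare", pct_min = 25),
               "no target gene")
})

test_that("quartile_coexpression is calibrated under anchor-independent targets", {
  set.seed(46)
  pvals <- vapply(1:60, function(i) {
    n <- 200
    v <- cbind(anchor = rexp(n), matrix(rexp(n * 6), n, 6))
    colnames(v) <- c("anchor", paste0("t", 1:6))
    rownames(v) <- paste0("c", 1:n)
    quartile_coexpression(em_from_values(v), "anchor",
                          paste0("t", 1:6))$friedman_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("dunn_vs_control matches the rank-based closed form", {
  set.seed(47)
  m <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("Q", 1:4)))
  d <- dunn_vs_control(m, "Q1")
  rk <- t(apply(m, 1, rank))
  se <- sqrt(4 * 5 / (6 * 12))
  for (j in 2:4) {
    z_want <- (mean(rk[, j]) - mean(rk[, 1])) / se
    expect_equal(d$z[d$comparison == paste0("Q", j, " vs Q1")], z_want,
                 tolerance = 1e-12)
  }
  expect_equal(d$p_adjusted, p.adjust(d$p_value, "holm"), tolerance = 1e-12)
})

test_that("project_modules reports one row per module with coherent stats", {
  ds <- simulate_aging_dataset(sim_config(n_cells_per_age = 150, seed = 19))
  em <- lognormalize(ds$counts)
  mods <- split(ds$truth$genes$gene, ds$truth$genes$module)
  mods <- mods[names(mods) != "background"]
  old <- ds$counts$cell_ids[ds$counts$cell_meta$age == 24]
  young <- ds$counts$cell_ids[ds$counts$cell_meta$age == 6]
  proj <- project_modules(em, mods, old, young)
  expect_equal(nrow(proj), 5)
  # the homeostatic module falls with age, the inflammation module rises
  expect_lt(proj$mean_log2fc[proj$module == "1"], 0)
  expect_gt(proj$mean_log2fc[proj$module == "4"], 0)
})
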