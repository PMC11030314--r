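#' Default pipeline configuration
#'
#' A nested list of all stage parameters with their standard values: QC
#' thresholds (genes > 1000, counts > 10000, mito < 5 for real data), 2500
#' variable genes, 25 principal components, k = 15 neighbors, clustering
#' resolution 0.4, Moran q cutoff 0.005, and the contrast pseudocount 0.01.
#' For synthetic runs (`simulate = TRUE`) the QC thresholds are scaled to
#' the simulator's gene panel (~150 genes), since the real-data floors would
#' remove every simulated cell.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param simulate simulate the input dataset instead of reading one.
#' @return a `RunConfig` list, ready for [validate_config()] /
#'   [run_pipeline()].
#' @export
default_run_config <- function(seed = 1, simulate = TRUE) {
  list(
    seed = seed,
    simulate = simulate,
    input = list(path = NULL, format = "mtx_dir"),
    sim = if (simulate) unclass(sim_config(seed = stage_seed(seed, "simulate"))) else NULL,
    qc = if (simulate) list(min_genes = 10, min_counts = 50, max_mito_pct = 5)
         else list(min_genes = 1000, min_counts = 10000, max_mito_pct = 5),
    normalize = list(scale_factor = 1e4),
    hvg = list(n_top = if (simulate) 60 else 2500),
    pca = list(n_components = if (simulate) 3 else 25),
    graph = list(k = 15),
    cluster = list(resolution = 0.4),
    trajectory = list(n_segments = 10, max_iter = 100, tol = 1e-4,
                      t_split = 0.6, k_branches = 2,
                      root_age = NULL),
    modules = list(method = "analytic", n_perm = 999, q_cutoff = 0.005,
                   resolution = 1, k_gene = 10, n_bins = 20),
    contrast = list(delta = NULL, epsilon = 0.01),
    run_until = "project",
    outdir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Reports unknown keys, out-of-range values and unreachable input paths
#' before any compute.
#'
#' @param cfg a `RunConfig` list.
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  known <- names(default_run_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    errs <- c(errs, paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a single number")
  if (isTRUE(cfg$simulate)) {
    res <- tryCatch({ do.call(sim_config, cfg$sim); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) errs <- c(errs, res)
  } else {
    if (is.null(cfg$input$path)) errs <- c(errs, "input$path is required when simulate = FALSE")
    else if (!file.exists(cfg$input$path))
      errs <- c(errs, paste("input path not found:", cfg$input$path))
  }
  chk(cfg$qc$min_genes >= 0, "qc$min_genes must be >= 0")
  chk(cfg$qc$min_counts >= 0, "qc$min_counts must be >= 0")
  chk(cfg$qc$max_mito_pct > 0, "qc$max_mito_pct must be > 0")
  chk(cfg$normalize$scale_factor > 0, "normalize$scale_factor must be > 0")
  chk(cfg$hvg$n_top >= 2, "hvg$n_top must be >= 2")
  chk(cfg$pca$n_components >= 2, "pca$n_components must be >= 2")
  chk(cfg$graph$k >= 1, "graph$k must be a positive integer")
  chk(cfg$cluster$resolution > 0, "cluster$resolution must be > 0")
  chk(cfg$trajectory$t_split >= 0 && cfg$trajectory$t_split < 1,
      "trajectory$t_split must be in [0, 1)")
  chk(cfg$modules$q_cutoff > 0 && cfg$modules$q_cutoff < 1,
      "modules$q_cutoff must be in (0, 1)")
  chk(cfg$modules$resolution > 0, "modules$resolution must be > 0")
  if (!is.null(cfg$contrast$delta))
    chk(abs(cfg$contrast$delta) <= 1, "contrast$delta must satisfy |delta| <= 1")
  chk(is.null(cfg$run_until) ||
        cfg$run_until %in% c("simulate", "qc", "pca", "cluster", "trajectory",
                             "modules", "project"),
      "run_until must name a pipeline stage")
  errs
}

#' Read or write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return for `read_run_config`, a `RunConfig` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(seed = cfg$seed %||% 1,
                             simulate = isTRUE(cfg$simulate %||% TRUE))
  utils::modifyList(base, cfg)
}

#' @rdname read_run_config
#' @param cfg a `RunConfig` list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> QC -> normalize -> HVG/scale/PCA ->
#' kNN graph + Louvain clusters -> principal-curve pseudotime (rooted in the
#' youngest age group) -> branch split -> Moran's I screen -> gene modules
#' -> optional contrast projection. Stage outputs are written as plain-text
#' tables under `outdir` (if set) together with a JSON manifest of seeds,
#' parameters and per-stage dimensions. Re-running the same config
#' reproduces all outputs exactly.
#'
#' @param cfg a `RunConfig` (see [default_run_config()]).
#' @return a list of stage results: `counts`, `truth` (synthetic runs),
#'   `em`, `embedding`, `graph`, `partition`, `trajectory`, `autocorr`,
#'   `modules`, `projection` (when a contrast is configured), `manifest`.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  errs <- validate_config(cfg)
  if (length(errs) > 0)
    stop("invalid config:\n", paste("-", errs, collapse = "\n"))
  manifest <- list(seed = cfg$seed, stages = list(),
                   parameters = cfg, timestamp = as.character(Sys.time()))
  out <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }

  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", do.call(sim_config, cfg$sim))
    ds <- stage("simulate", simulate_aging_dataset(sim))
    out$counts <- ds$counts; out$truth <- ds$truth
  } else {
    out$counts <- stage("read", read_counts(cfg$input$path, cfg$input$format))
  }
  manifest$stages$input <- dim(out$counts$counts)
  halt <- function(at) {
    done <- identical(cfg$run_until %||% "project", at)
    if (done) {
      out$manifest <<- manifest
      if (!is.null(cfg$outdir)) .write_pipeline_outputs(out, cfg$outdir)
    }
    done
  }
  if (halt("simulate")) return(out)

  out$counts_qc <- stage("qc", qc_filter(out$counts, cfg$qc$min_genes,
                                         cfg$qc$min_counts, cfg$qc$max_mito_pct))
  manifest$stages$qc <- dim(out$counts_qc$counts)
  if (halt("qc")) return(out)

  out$em <- stage("normalize", lognormalize(out$counts_qc,
                                            cfg$normalize$scale_factor))
  hvg <- stage("hvg", select_hvg(out$counts_qc,
                                 min(cfg$hvg$n_top, length(out$counts_qc$gene_ids))))
  scaled <- stage("scale", scale_center(out$em, hvg))
  out$embedding <- stage("pca", pca_embed(scaled, cfg$pca$n_components))
  manifest$stages$pca <- dim(out$embedding$coords)
  if (halt("pca")) return(out)

  out$graph <- stage("graph", knn_graph(out$embedding, cfg$graph$k))
  out$partition <- stage("cluster",
                         louvain_partition(out$graph, cfg$cluster$resolution,
                                           seed = stage_seed(cfg$seed, "cluster")))
  manifest$stages$clusters <- length(unique(out$partition$labels))
  if (halt("cluster")) return(out)

  traj <- stage("trajectory",
                fit_principal_curve(out$embedding, cfg$trajectory$n_segments,
                                    cfg$trajectory$max_iter, cfg$trajectory$tol))
  root_age <- cfg$trajectory$root_age %||%
    if ("age" %in% colnames(out$counts_qc$cell_meta))
      min(out$counts_qc$cell_meta$age) else NULL
  if (!is.null(root_age)) {
    roots <- out$counts_qc$cell_ids[out$counts_qc$cell_meta$age == root_age]
    traj <- stage("trajectory", orient_by_root(traj, roots))
  }
  traj <- stage("trajectory",
                split_terminal_branches(traj, out$embedding,
                                        cfg$trajectory$t_split,
                                        cfg$trajectory$k_branches,
                                        seed = stage_seed(cfg$seed, "branches")))
  out$trajectory <- traj
  if (halt("trajectory")) return(out)

  out$autocorr <- stage("moran",
                        morans_test(out$em, out$graph,
                                    method = cfg$modules$method,
                                    n_perm = cfg$modules$n_perm,
                                    seed = stage_seed(cfg$seed, "moran")))
  sig <- significant_genes(out$autocorr, cfg$modules$q_cutoff)
  manifest$stages$significant_genes <- nrow(sig)
  out$modules <- stage("modules",
                       discover_modules(out$em, traj, sig,
                                        resolution = cfg$modules$resolution,
                                        k_gene = cfg$modules$k_gene,
                                        n_bins = cfg$modules$n_bins,
                                        seed = stage_seed(cfg$seed, "modules")))
  manifest$stages$modules <- length(out$modules$modules)
  if (halt("modules")) return(out)

  if (!is.null(cfg$contrast$delta)) {
    if (!isTRUE(cfg$simulate))
      stop("pipeline stage 'project' failed: contrasts require a synthetic run")
    sim <- do.call(sim_config, cfg$sim)
    treated <- stage("project",
                     simulate_condition_shift(out$truth, sim, cfg$contrast$delta))
    joint <- stage("project", .bind_counts(out$counts_qc, treated$counts))
    em2 <- stage("project", lognormalize(joint, cfg$normalize$scale_factor))
    out$projection <- stage("project",
                            project_modules(em2, out$modules,
                                            group_a_cells = treated$counts$cell_ids,
                                            group_b_cells = out$counts_qc$cell_ids,
                                            epsilon = cfg$contrast$epsilon))
    manifest$stages$projection <- nrow(out$projection)
  }

  out$manifest <- manifest
  if (!is.null(cfg$outdir)) .write_pipeline_outputs(out, cfg$outdir)
  out
}

.bind_counts <- function(a, b) {
  stopifnot(identical(a$gene_ids, b$gene_ids))
  counts <- rbind(a$counts, b$counts)
  meta_cols <- intersect(colnames(a$cell_meta), colnames(b$cell_meta))
  meta <- rbind(a$cell_meta[, meta_cols, drop = FALSE],
                b$cell_meta[, meta_cols, drop = FALSE])
  count_matrix(counts, cell_ids = c(a$cell_ids, b$cell_ids),
               gene_ids = a$gene_ids, cell_meta = meta)
}

.write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$truth)) {
    w(out$truth$cells, "truth_cells.tsv")
    w(out$truth$genes, "truth_genes.tsv")
  }
  if (!is.null(out$trajectory))
    w(data.frame(cell_id = names(out$trajectory$pseudotime),
                 pseudotime = out$trajectory$pseudotime,
                 branch = out$trajectory$branch_labels %||% NA),
      "pseudotime.tsv")
  if (!is.null(out$partition))
    w(data.frame(cell_id = names(out$partition$labels),
                 community = out$partition$labels), "clusters.tsv")
  if (!is.null(out$autocorr)) w(as.data.frame(out$autocorr), "autocorrelation.tsv")
  if (!is.null(out$modules))
    w(data.frame(gene = names(out$modules$assignment),
                 module = out$modules$assignment), "modules.tsv")
  if (!is.null(out$projection)) w(out$projection, "module_projection.tsv")
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(outdir)
}
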