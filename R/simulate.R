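#' Configuration for the synthetic aging dataset
#'
#' Defines the generative world the pipeline is tested against: four age
#' groups (6, 12, 18, 24 months) coupled to a latent aging pseudotime
#' t in [0, 1] via overlapping Gaussians (so ages mix along t), five planted
#' gene modules with the qualitative temporal grammar of microglial aging —
#' a declining homeostatic program, a transient mid-trajectory stress
#' program, late translation and inflammation ramps on the main
#' (inflammatory) branch, and an independent myeloid-activation branch
#' program — plus flat background genes. Counts are negative binomial
#' around library-size-scaled profile means.
#'
#' @param n_cells_per_age cells per age group (default 500, ~2000 total).
#' @param ages ordered age labels in months.
#' @param pseudotime_means,pseudotime_sd per-age mean (non-decreasing) and
#'   common sd of the latent pseudotime before clamping to [0, 1].
#' @param n_genes_per_module genes in each of the 5 modules.
#' @param n_background_genes trajectory-independent genes.
#' @param profile_params list of temporal profile parameters: `decline_slope`
#'   (module 1, linear decline `a (1 - t)`), `bump_center`, `bump_width`
#'   (module 2 Gaussian bump), `ramp_mid`, `ramp_steepness` (length-2, the
#'   module 3 and 4 logistic ramps), `amplitude` (length-5 per-module
#'   amplitudes), `offset` (length-5 baselines), `background_level`
#'   (background-gene mean as a multiple of `base_expression`; the default
#'   gives the trajectory-independent genes enough aggregate mass that
#'   per-cell totals — and hence log-normalized background values — stay
#'   nearly flat along the trajectory).
#' @param branch_threshold pseudotime beyond which cells may take the
#'   myeloid branch.
#' @param branch_prob probability a late cell takes the myeloid branch.
#' @param nb_dispersion negative-binomial size parameter (inverse
#'   overdispersion); `Inf` gives the Poisson limit.
#' @param libsize_logmean,libsize_logsd log-normal library-size factors.
#' @param base_expression mean count scale of a unit-profile gene.
#' @param gene_scale_sd sd of the per-gene log-normal expression scale
#'   (fixed per gene; 0 makes genes within a module identically scaled).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_cells_per_age = 500,
                       ages = c(6, 12, 18, 24),
                       pseudotime_means = c(0.20, 0.40, 0.60, 0.80),
                       pseudotime_sd = 0.13,
                       n_genes_per_module = 10,
                       n_background_genes = 100,
                       profile_params = list(
                         decline_slope = 3.0,
                         bump_center = 0.45, bump_width = 0.12,
                         ramp_mid = c(0.5, 0.8),
                         ramp_steepness = c(20, 20),
                         amplitude = c(1.0, 3.0, 2.5, 3.0, 3.0),
                         offset = c(0.3, 0.3, 0.3, 0.2, 0.3),
                         background_level = 2),
                       branch_threshold = 0.6,
                       branch_prob = 0.25,
                       nb_dispersion = 2,
                       libsize_logmean = 0,
                       libsize_logsd = 0.3,
                       base_expression = 2,
                       gene_scale_sd = 0.2,
                       seed = 1) {
  cfg <- as.list(environment())
  .check(n_cells_per_age >= 1, "n_cells_per_age")
  .check(length(ages) == length(pseudotime_means), "pseudotime_means")
  .check(!is.unsorted(pseudotime_means), "pseudotime_means")
  .check(pseudotime_sd > 0, "pseudotime_sd")
  .check(n_genes_per_module >= 1, "n_genes_per_module")
  .check(n_background_genes >= 0, "n_background_genes")
  .check(branch_prob >= 0 && branch_prob <= 1, "branch_prob")
  .check(branch_threshold > 0 && branch_threshold < 1, "branch_threshold")
  .check(nb_dispersion > 0, "nb_dispersion")
  .check(libsize_logsd >= 0, "libsize_logsd")
  .check(base_expression > 0, "base_expression")
  .check(gene_scale_sd >= 0, "gene_scale_sd")
  pp <- profile_params
  .check(pp$decline_slope > 0, "profile_params$decline_slope")
  .check(pp$bump_width > 0, "profile_params$bump_width")
  .check(length(pp$ramp_mid) == 2 && length(pp$ramp_steepness) == 2,
         "profile_params$ramp_mid")
  .check(length(pp$amplitude) == 5 && all(pp$amplitude > 0),
         "profile_params$amplitude")
  .check(length(pp$offset) == 5 && all(pp$offset >= 0),
         "profile_params$offset")
  .check((pp$background_level %||% 1) > 0, "profile_params$background_level")
  structure(cfg, class = "SimConfig")
}

.check <- function(ok, field) {
  if (!isTRUE(ok)) stop("invalid simulation parameter: ", field, call. = FALSE)
}

# Module mean profiles (multipliers of base_expression), given pseudotime t
# and branch label. Modules 3-4 ramp on the inflammatory branch only: for
# myeloid cells their input is frozen at the branch point. Module 5 is a
# branch indicator.
.module_profile <- function(module, t, branch, cfg) {
  pp <- cfg$profile_params
  amp <- pp$amplitude; off <- pp$offset
  t_main <- ifelse(branch == "myeloid", pmin(t, cfg$branch_threshold), t)
  switch(as.character(module),
         "1" = off[1] + amp[1] * pp$decline_slope * (1 - t),
         "2" = off[2] + amp[2] * exp(-(t - pp$bump_center)^2 /
                                       (2 * pp$bump_width^2)),
         "3" = off[3] + amp[3] / (1 + exp(-pp$ramp_steepness[1] *
                                            (t_main - pp$ramp_mid[1]))),
         "4" = off[4] + amp[4] / (1 + exp(-pp$ramp_steepness[2] *
                                            (t_main - pp$ramp_mid[2]))),
         "5" = off[5] + amp[5] * (branch == "myeloid"),
         "background" = rep(pp$background_level %||% 1, length(t)))
}

#' Expected (noise-free) expression means of the generator
#'
#' The cells x genes matrix of generative means before library-size scaling
#' and per-gene scale factors — the analytic object behind the limit tests.
#'
#' @param cfg a `SimConfig`.
#' @param t pseudotime per cell.
#' @param branch branch label per cell (`trunk`, `inflammatory`, `myeloid`).
#' @return cells x genes matrix of `base_expression * profile`.
#' @export
sim_expected_means <- function(cfg, t, branch) {
  gm <- .sim_gene_table(cfg)
  mu <- matrix(0, length(t), nrow(gm))
  for (k in seq_len(nrow(gm)))
    mu[, k] <- cfg$base_expression * .module_profile(gm$module[k], t, branch, cfg)
  colnames(mu) <- gm$gene
  mu
}

.sim_gene_table <- function(cfg) {
  g <- cfg$n_genes_per_module
  modules <- c(rep(as.character(1:5), each = g),
               rep("background", cfg$n_background_genes))
  gene <- c(sprintf("mod%d_g%02d", rep(1:5, each = g), rep(seq_len(g), 5)),
            if (cfg$n_background_genes > 0)
              sprintf("bg_g%03d", seq_len(cfg$n_background_genes)))
  data.frame(gene = gene, module = modules, stringsAsFactors = FALSE)
}

#' Simulate the synthetic aging dataset
#'
#' Draws latent pseudotimes per age group, assigns late cells to the
#' myeloid branch with probability `branch_prob`, and emits negative
#' binomial counts around library-size-scaled module profiles. Deterministic
#' given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (a `CountMatrix` whose `cell_meta` carries
#'   `age`) and `truth` (a `SimTruth`: `cells` data.frame with `cell_id`,
#'   `age`, `pseudotime`, `branch`, `libsize_factor`; `genes` data.frame
#'   with `gene`, `module`, `scale`; `delta` = 0).
#' @export
simulate_aging_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    n_age <- length(cfg$ages)
    n <- cfg$n_cells_per_age * n_age
    age <- rep(cfg$ages, each = cfg$n_cells_per_age)
    mu_t <- rep(cfg$pseudotime_means, each = cfg$n_cells_per_age)
    t <- pmin(1, pmax(0, stats::rnorm(n, mu_t, cfg$pseudotime_sd)))
    branch <- ifelse(t < cfg$branch_threshold, "trunk", "inflammatory")
    late <- which(t >= cfg$branch_threshold)
    takes <- stats::runif(length(late)) < cfg$branch_prob
    branch[late[takes]] <- "myeloid"
    gm <- .sim_gene_table(cfg)
    gm$scale <- exp(stats::rnorm(nrow(gm), 0, cfg$gene_scale_sd))
    libsize <- exp(stats::rnorm(n, cfg$libsize_logmean, cfg$libsize_logsd))
    cell_id <- sprintf("cell_%05d", seq_len(n))
    truth <- list(cells = data.frame(cell_id = cell_id, age = age,
                                     pseudotime = t, branch = branch,
                                     libsize_factor = libsize,
                                     stringsAsFactors = FALSE),
                  genes = gm, delta = 0)
    class(truth) <- "SimTruth"
    meta <- data.frame(age = age, condition = "control",
                       row.names = cell_id, stringsAsFactors = FALSE)
    counts <- .draw_counts(cfg, t, branch, libsize, gm, cell_id, meta)
    list(counts = counts, truth = truth)
  })
}

.draw_counts <- function(cfg, t, branch, libsize, gm, cell_id, meta) {
  n <- length(t)
  mu <- sim_expected_means(cfg, t, branch)
  mu <- mu * libsize  # recycles down columns: per-cell factor
  mu <- sweep(mu, 2, gm$scale, "*")
  draws <- if (is.infinite(cfg$nb_dispersion))
    stats::rpois(length(mu), lambda = mu)
  else
    stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion)
  x <- matrix(draws, nrow = n)
  dimnames(x) <- list(cell_id, gm$gene)
  count_matrix(x, cell_meta = meta)
}

#' Simulate a pseudotime-shifted ("treated") condition arm
#'
#' Re-draws the cells of `base_truth` from the same generative model at
#' pseudotime `t + delta` (clamped to [0, 1]) — the synthetic analogue of a
#' systemic intervention advancing cells along the aging trajectory. Trunk
#' cells whose shifted pseudotime crosses the branch threshold take the
#' myeloid branch with the configured probability.
#'
#' @param base_truth the `SimTruth` of a [simulate_aging_dataset()] run.
#' @param cfg the same `SimConfig`.
#' @param delta pseudotime shift, |delta| <= 1.
#' @param seed seed for the treated arm (default derived from the config
#'   seed).
#' @return list with `counts` and `truth` for the treated arm; the truth
#'   records `delta` and the shifted pseudotimes.
#' @export
simulate_condition_shift <- function(base_truth, cfg, delta, seed = NULL) {
  stopifnot(inherits(base_truth, "SimTruth"), inherits(cfg, "SimConfig"))
  if (abs(delta) > 1) stop("invalid simulation parameter: delta (|delta| <= 1)")
  if (is.null(seed)) seed <- stage_seed(cfg$seed, "condition_shift")
  with_seed(seed, {
    cells <- base_truth$cells
    t2 <- pmin(1, pmax(0, cells$pseudotime + delta))
    branch <- cells$branch
    crossed <- which(branch == "trunk" & t2 >= cfg$branch_threshold)
    takes <- stats::runif(length(crossed)) < cfg$branch_prob
    branch[crossed] <- ifelse(takes, "myeloid", "inflammatory")
    reverted <- which(branch != "trunk" & t2 < cfg$branch_threshold)
    branch[reverted] <- "trunk"
    gm <- base_truth$genes
    libsize <- exp(stats::rnorm(nrow(cells), cfg$libsize_logmean,
                                cfg$libsize_logsd))
    cell_id <- sprintf("treated_%05d", seq_len(nrow(cells)))
    truth <- list(cells = data.frame(cell_id = cell_id, age = cells$age,
                                     pseudotime = t2, branch = branch,
                                     libsize_factor = libsize,
                                     stringsAsFactors = FALSE),
                  genes = gm, delta = delta)
    class(truth) <- "SimTruth"
    meta <- data.frame(age = cells$age, condition = "treated",
                       row.names = cell_id, stringsAsFactors = FALSE)
    counts <- .draw_counts(cfg, t2, branch, libsize, gm, cell_id, meta)
    list(counts = counts, truth = truth)
  })
}

#' Simulate an image fixture with known puncta truth
#'
#' Lays out `n_cells` non-overlapping square cells on a grid and renders
#' the requested puncta as compact 8-connected blobs of exactly the
#' specified pixel area and per-pixel intensity, fully inside their cells.
#'
#' @param n_cells number of cells (labels 1..n_cells).
#' @param puncta_spec data.frame (or list coercible to one) with columns
#'   `cell`, `area_px` (>= 1), `intensity` (> 0); several puncta per cell
#'   are laid side by side with a 1-pixel gap.
#' @param resolution_um_per_px physical pixel size.
#' @param cell_size side length of each square cell in pixels; `NULL`
#'   auto-sizes to fit the largest puncta load.
#' @param seed kept for interface symmetry; the layout is deterministic.
#' @return an `ImageFixture`: list with `label_mask`, `puncta_image`,
#'   `truth` (data.frame: `cell`, `area_px`, `intensity`,
#'   `total_intensity`), `resolution_um_per_px`.
#' @export
simulate_image_fixture <- function(n_cells, puncta_spec = NULL,
                                   resolution_um_per_px = 0.312,
                                   cell_size = NULL, seed = NULL) {
  stopifnot(n_cells >= 1)
  spec <- if (is.null(puncta_spec) || NROW(puncta_spec) == 0)
    data.frame(cell = integer(0), area_px = integer(0), intensity = numeric(0))
  else as.data.frame(puncta_spec)
  if (nrow(spec) > 0) {
    stopifnot(all(c("cell", "area_px", "intensity") %in% colnames(spec)))
    if (any(spec$area_px < 1)) stop("puncta areas must be >= 1 px")
    if (any(spec$cell < 1 | spec$cell > n_cells)) stop("puncta cell id out of range")
  }
  sides <- ceiling(sqrt(spec$area_px))
  # per-cell footprint needed: puncta in a row, 1 px gaps, 2 px margin
  need_w <- vapply(seq_len(n_cells), function(k) {
    s <- sides[spec$cell == k]
    if (length(s) == 0) 0 else sum(s) + (length(s) - 1) + 4
  }, numeric(1))
  need_h <- vapply(seq_len(n_cells), function(k) {
    s <- sides[spec$cell == k]
    if (length(s) == 0) 0 else max(s) + 4
  }, numeric(1))
  auto <- max(12, need_w, need_h)
  if (is.null(cell_size)) cell_size <- auto
  if (any(need_w > cell_size) || any(need_h > cell_size))
    stop("puncta exceed the cell footprint (cell_size too small)")
  gap <- 2
  per_row <- ceiling(sqrt(n_cells))
  rows <- ceiling(n_cells / per_row)
  H <- rows * (cell_size + gap) + gap
  W <- per_row * (cell_size + gap) + gap
  mask <- matrix(0L, H, W)
  img <- matrix(0, H, W)
  truth <- data.frame(cell = integer(0), area_px = integer(0),
                      intensity = numeric(0), total_intensity = numeric(0))
  for (k in seq_len(n_cells)) {
    gr <- (k - 1) %/% per_row
    gc <- (k - 1) %% per_row
    r0 <- gap + gr * (cell_size + gap) + 1
    c0 <- gap + gc * (cell_size + gap) + 1
    mask[r0:(r0 + cell_size - 1), c0:(c0 + cell_size - 1)] <- k
    ps <- spec[spec$cell == k, , drop = FALSE]
    coff <- c0 + 2
    for (pi in seq_len(nrow(ps))) {
      a <- ps$area_px[pi]
      s <- ceiling(sqrt(a))
      # compact row-major fill of a s x s square: connected, exactly a px
      fill_r <- rep(seq_len(s), each = s)[seq_len(a)]
      fill_c <- rep(seq_len(s), times = s)[seq_len(a)]
      rr <- r0 + 2 + fill_r - 1
      cc <- coff + fill_c - 1
      img[cbind(rr, cc)] <- ps$intensity[pi]
      truth <- rbind(truth, data.frame(cell = k, area_px = a,
                                       intensity = ps$intensity[pi],
                                       total_intensity = a * ps$intensity[pi]))
      coff <- coff + s + 1
    }
  }
  structure(list(label_mask = mask, puncta_image = img, truth = truth,
                 resolution_um_per_px = resolution_um_per_px),
            class = "ImageFixture")
}
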