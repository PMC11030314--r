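---
title: "Reconstructing microglial aging trajectories: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing microglial aging trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtraj)
```

## The scientific problem

Microglia — the brain's resident macrophages — do not jump from a
homeostatic to an inflamed state during aging; they appear to pass through
intermediate transcriptional states (a transient stress-response program, a
surge in translational machinery) before terminal inflammatory activation.
Detecting those intermediates from single-cell RNA-seq requires ordering
cells along a latent *aging pseudotime*, asking which genes vary coherently
along that ordering, grouping them into coregulated modules, and then
projecting independent perturbations (heterochronic parabiosis, disease
models, genotype contrasts, in vitro treatments) onto the modules to ask
whether the perturbation advances or retards the trajectory.

`microtraj` implements that chain end to end on cells-by-genes count
matrices, together with the puncta-based image quantification used to
corroborate the transcriptional states in tissue, and a synthetic-data
generator that plants the assumed statistical structure so every stage can
be tested against ground truth.

## The pipeline and its models

### QC, normalization, feature selection, embedding

Cells are retained when they *strictly* satisfy all of: detected genes >
`min_genes` (default 1000), total counts > `min_counts` (default 10000),
and mitochondrial percentage < `max_mito_pct` (default 5; mitochondrial
genes are flagged by the mouse `mt-` prefix unless a `mito` column is
supplied). A separate raw-count marker gate (`marker_gate()`, defaults in
`microglia_gates()`: Hexb > 4, Tmem119 > 1, Cx3cr1 > 4, Top2a < 1,
Mki67 < 1) isolates non-proliferating microglia in genotype datasets.

Normalization is `ln(1 + count / total * scale_factor)` with
`scale_factor = 10^4` — the de facto single-cell convention. Variable genes
are ranked by variance-stabilized standardized variance: a loess fit (span
0.3, degree 2) of `log10(variance)` on `log10(mean)` supplies each gene's
expected standard deviation; counts standardized by it are clipped at
`sqrt(n_cells)` and their variance is the ranking statistic. Selected genes
are centered and scaled per gene (clip ±10) before PCA. PCA signs are fixed
by forcing each component's largest-magnitude loading positive, so results
are reproducible across platforms.

### Cell graph and clustering

The kNN graph (default k = 15, Euclidean metric in PC space) is
union-symmetrized with binary weights: an edge exists when either endpoint
names the other among its k nearest neighbors. Binary weights keep the
Moran's I weight total interpretable and the permutation null simple.
Communities are found by Louvain modularity optimization with a resolution
parameter (default 0.4, the value used for whole-dataset clustering in this
analysis tradition); the backing implementation is `igraph`, and the
reported modularity is additionally recomputable from the package's own
closed-form `graph_modularity()`.

### Trajectory: a principal curve with an anchored root

The trajectory engine is an iterative piecewise-linear principal curve —
project cells onto the current curve, re-estimate each node as the mean of
the cells projecting into its arc-length bin, smooth the node sequence with
a (1/4, 1/2, 1/4) kernel, repeat until the mean squared projection distance
stabilizes. Pseudotime is the normalized arc-length of each cell's
projection. A principal curve is used instead of a full principal graph
because the two approaches were concordant on these data and a curve is
analyzable and testable at desk scale.

Two numerical choices matter:

* **Number of segments.** The default is 10, not a large value. With a few
  thousand cells embedded in 3–25 PCs, most trailing dimensions are
  isotropic noise; a 50-node curve has enough freedom to chase that noise,
  which empirically scrambles the arc-length ordering (rank correlation
  with the planted ordering drops from ~0.95 to ~0.05 on the bundled
  simulator). Ten nodes track the backbone and leave the noise alone.
* **Monotone objective.** The node-averaging + smoothing update is not
  guaranteed to decrease the objective, so a refinement that would increase
  it is rejected and the fit stops at the previous curve. The objective
  trace is therefore non-increasing by construction, which is also asserted
  as a property test.

The root is anchored by `orient_by_root()`: pseudotime is flipped exactly
when the designated root cells (the youngest age group, by default) have a
higher mean pseudotime than the rest, guaranteeing root cells end up early.
Terminal branching is an explicit, seeded rule rather than a manual pick:
cells with pseudotime ≥ `t_split` (default 0.6) are k-means-clustered in
embedding space (default k = 2) and labeled `branch_A`, `branch_B` by
decreasing size; a degenerate (unseparated) terminal set is flagged rather
than hidden.

### Module discovery: Moran's I, then Louvain on a gene graph

Trajectory dependence is screened by Moran's I on the cell graph:

`I = (n / W) * sum_ij w_ij (x_i - mean(x)) (x_j - mean(x)) / sum_i (x_i - mean(x))^2`

with `W` the total weight. Three testing modes are provided: seeded
permutation (`p = (1 + #[I_perm >= I_obs]) / (1 + n_perm)`, one-sided for
positive autocorrelation — focal expression is the alternative of
interest), an analytic z-score under the randomization-assumption variance
(used at scale for speed), and exhaustive enumeration for tiny graphs
(n ≤ 8), which the tests compare against an independent enumerator.
Constant genes are flagged with p = 1, never NaN. Genes pass the screen at
BH q < 0.005.

Significant genes are smoothed along the trajectory by **equal-count**
(quantile) pseudotime bins — 20 bins over the main trajectory plus separate
bins for the off-trajectory branch when branch labels exist. Equal-count
bins were chosen over equal-width bins deliberately: with equal-width bins
the sparse tail bins contribute almost pure noise (and empty bins need
interpolation), which at desk scale destroyed the within-module profile
correlations that the gene graph is built from. Pairwise Pearson
correlations of the smoothed profiles define a kNN gene graph (k = 10,
union-symmetrized, edge weight = correlation, non-positive correlations
dropped), partitioned by Louvain.

The gene-graph resolution default is 1, not the 0.0078 used by the original
Monocle-based analysis. That constant is specific to Monocle's UMAP-space
gene graph; on this package's correlation-kNN gene graph a resolution that
small merges everything into one module (the null term vanishes), so the
package treats resolution as a graph-specific constant and documents 1 as
the default for its own graph construction. Modules are numbered by where
their mean profile peaks along the trajectory, so module 1 is the
early/declining (homeostatic) program and the last module is the
off-branch program — matching the field's reading order. `top_module_genes()`
returns each module's 10 most significant genes (ascending q, ties by gene
id), the heatmap representatives.

### Projections, dotplots, quartile co-expression

A contrast (treated vs control, old vs young, knockout vs wild type) is
projected onto a module as the per-gene `log2((mean_a + eps)/(mean_b + eps))`
on log-normalized values (eps = 0.01 by default: no conventional value
exists for this statistic, and on the log-normalized scale 0.01 is small
relative to any expressed gene), followed by a one-sample t-test of the module's gene
fold changes against 0 — the null of no change in log2 space. The t
statistic is invariant to positive rescaling of the fold changes, which is
asserted as a property. Degenerate inputs (zero variance) are returned
flagged, not as exceptions.

Dotplot statistics are the percent of cells with a positive normalized
value and the mean normalized value per (gene, group). The quartile
("autocrine") analysis bins cells into near-equal quartiles of an anchor
gene's expression (ties broken by cell id, sizes differing by at most 1),
keeps target genes expressed in > 25% of cells, z-scores each gene's four
quartile means, and tests genes-by-quartiles with a Friedman test followed
by Dunn's comparisons against Q1. Dunn's test is implemented directly
(within-block ranks, `z = (Rbar_t - Rbar_c) / sqrt(k(k+1)/(6n))`) with Holm
correction, as no installed package provides it.

### Differential expression and overlap

Per-gene two-sided Mann-Whitney U tests with tie-corrected normal
approximation (continuity correction off by default, switchable); exact
enumeration replaces the approximation when both groups have ≤ 8 cells.
Prefilters default to min_pct = 10 and no fold-change floor. Gene-set
overlap significance is Pearson's chi-squared (1 df, no continuity
correction) on the 2×2 membership table over a configurable universe
(default: the tested genes); `concordant_sets()` restricts an overlap to
genes whose fold changes agree in sign.

### Image quantification

The formula-defined microscopy operators work on integer label masks
(0 = background, k = cell k) and intensity images. `percent_activated()`
thresholds the puncta channel, labels 8-connected components, intersects
them with each cell, and calls a cell activated iff a component contributes
at least `min_particle_px` pixels (default 100 px = 31.2 µm at the default
0.312 µm/pixel) *within* that cell — a punctum straddling two cells is
counted separately in each, since activation is evaluated per microglium.
`rnascope_normalized_count()` divides each cell's total puncta intensity by
the mean intensity of reference single puncta. `px_area_to_um()` applies
the printed linear pixel-to-micron equivalence; note the source protocol
states "100 pixels, equating to 31.2 µm", mixing an area count with a
length via the linear factor — the package implements the printed linear
equivalence and leaves the dimensional reading to the user.

## The synthetic world

`sim_config()` states the generative world once:

* Four age groups (6, 12, 18, 24 months), 500 cells each. Latent pseudotime
  per cell is Gaussian around age-specific means (0.20, 0.40, 0.60, 0.80;
  sd 0.13), clamped to [0, 1] — ages overlap along the trajectory, as they
  do in real data.
* Five modules of 10 genes: module 1 declines linearly (`a (1 - t)`,
  slope 3); module 2 is a Gaussian bump (center 0.45, width 0.12) — the
  transient stress program; modules 3 and 4 are logistic ramps (midpoints
  0.5 and 0.8, steepness 20) — translation then inflammation; module 5 is
  elevated only on the myeloid branch. Cells past pseudotime 0.6 take the
  myeloid branch with probability 0.25; modules 3–4 freeze at the branch
  point for myeloid cells, making the branch transcriptionally independent
  of the translation ramp.
* 100 flat background genes at twice the unit expression level
  (`background_level = 2`). This mass is deliberate: per-cell totals vary
  along the trajectory as modules rise and fall, so after library-size
  normalization "flat" genes inherit a spurious trajectory profile. The
  steeper module-1 decline and the heavier background baseline keep totals
  nearly balanced, which is what the stated world requires — background
  genes should fail the autocorrelation screen.
* Negative binomial counts (size 2; `Inf` gives the Poisson limit used in
  analytic checks), log-normal library sizes (sd 0.3), and a per-gene
  log-normal expression scale (sd 0.2).

Effect sizes are nowhere stated by the source analyses, so these defaults
were chosen once so that recovery is neither trivial nor impossible —
roughly: planted-module Moran's I around 0.15–0.35 against a null sd of
~0.01, pseudotime recoverable at rank correlation ~0.9, module recovery at
ARI ~0.95–1.0 — and are not revisited per test.

`simulate_condition_shift()` re-draws the same cells at `t + delta`
(clamped), the synthetic analogue of an intervention advancing cells along
the trajectory; trunk cells that cross the branch threshold branch with the
configured probability.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, regional heterogeneity, and zero-inflation beyond the NB. A green
recovery test therefore establishes that the chain is correctly wired and
statistically sound on NB data with smooth temporal programs — not that it
is robust to artifacts real datasets carry.

### Default analysis parameters for the synthetic run

`default_run_config(simulate = TRUE)` uses 60 variable genes and 3
principal components (against 2500 and 25 for a real dataset). The 150-gene
panel has a 3-dimensional latent structure (trajectory, bump curvature,
branch); including further PCs demonstrably injects per-gene noise into the
neighbor graph, which makes background genes autocorrelated with
*themselves* (their own noise helps position cells) and corrupts the
screen. The QC floors are likewise scaled (genes > 10, counts > 50) because
a 150-gene panel can never reach real-data totals.

## Numerical choices and degenerate inputs

* Ties in kNN distance break by cell index; quartile ties by cell id;
  q-value ties in top-gene lists by gene id; cluster-label ties by
  alphabetical marker-set name. Everything is deterministic given seeds.
* A single global seed fans out to per-stage seeds by a stable hash of the
  stage name (`stage_seed()`), kept below 2^31.
* Constant genes: Moran's I errors on a constant vector at the single-gene
  level (`morans_i`) but the gene screen flags them (p = 1); the shift test
  returns a flagged degenerate result; `scale_center` zeroes them.
* The permutation p-value includes the observed statistic in the null set
  (add-one form), so it is never 0.
* BH adjustment is one shared implementation (`bh_adjust()`), property
  tested against both the step-up definition and `p.adjust`.

## Known limitations

* The principal curve is single-rooted and cannot represent loops or
  multi-furcations; branch handling is a post-hoc k-means split.
* The analytic Moran mode assumes the randomization variance is adequate;
  at very small n or extreme kurtosis the permutation mode is preferable.
* The integration step used by the original genotype-dataset analysis
  (anchor-based batch correction) is out of scope; per-pool scaling is the
  substitute.
* Cell segmentation itself is out of scope for the image operators: they
  consume label masks produced upstream.
* The vst trend fit requires a handful of genes with positive variance to
  anchor the loess; below that it falls back to raw variance ranking.
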