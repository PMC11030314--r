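# microtraj

Reconstructing aging trajectories of hippocampal microglia from single-cell
RNA-seq, and quantifying the gene programs that change along them.

During aging, microglia progress from a homeostatic state through
intermediate states — a transient stress response, a surge in translational
machinery — toward inflammatory activation. `microtraj` implements the
analysis chain used to detect and exploit that progression:

1. **QC and preprocessing** — strict cell filters (genes > 1000, counts >
   10000, mitochondrial % < 5), raw-count marker gates for microglia,
   log normalization `ln(1 + c/T · 10⁴)`, vst variable-gene selection,
   per-gene scaling, sign-stabilized PCA.
2. **Cell graph and clustering** — union-symmetrized kNN graph in PC space;
   Louvain community detection with a resolution parameter; marker-based
   cluster typing.
3. **Pseudotime** — an iterative principal curve; pseudotime is normalized
   arc length, oriented so designated root cells (the youngest age group)
   sit at t ≈ 0; terminal cells are split into branches by a seeded k-means
   rule.
4. **Module discovery** — genes are screened for trajectory dependence by
   Moran's I graph autocorrelation,

   *I* = (n/W) Σᵢⱼ wᵢⱼ (xᵢ − x̄)(xⱼ − x̄) / Σᵢ (xᵢ − x̄)²,

   with permutation, analytic, and exhaustive testing modes and a BH
   q < 0.005 cutoff; significant genes are smoothed along pseudotime,
   correlated, and partitioned into coregulated modules by Louvain on a
   correlation-kNN gene graph. Each module reports its ten most significant
   genes.
5. **Module projection** — a contrast (old vs young, treated vs control,
   knockout vs wild type) is collapsed per module into per-gene
   log2 fold changes and a one-sample t-test against 0 (no change in log2
   space); dotplot statistics (percent expressing, average expression) and
   a quartile-binned co-expression analysis (Friedman + Dunn vs Q1, genes
   expressed in > 25% of cells) cover the remaining figure statistics.
6. **Differential expression and overlap** — Wilcoxon rank-sum DE with
   exact small-sample enumeration, and χ² significance of gene-set overlap
   on a 2×2 membership table.
7. **Image quantification** — puncta-threshold activation scoring (a cell
   is activated iff an 8-connected puncta component of ≥ 100 px lies within
   it; 100 px ≡ 31.2 µm at 0.312 µm/pixel), mean intensity per cell mask,
   and RNAscope puncta-intensity-normalized counts.
8. **Synthetic data** — a negative-binomial generator that plants the
   assumed structure (4 age groups coupled to a latent pseudotime, five
   modules: decline / bump / two late ramps / an independent branch
   program, flat background genes, log-normal library sizes) with full
   ground truth, so every stage is testable against recovery.

## Worked example

```r
library(microtraj)

cfg <- default_run_config(seed = 1)   # synthetic run, ~2000 cells
cfg$contrast$delta <- 0.3             # add a pseudotime-advanced "treated" arm
res <- run_pipeline(cfg)

res$modules
#> GeneModules: 51 genes in 5 modules (resolution 1)
#>  1  2  3  4  5
#> 11 10 10 10 10

res$projection
#>   module n_genes mean_log2fc t_statistic  p_value
#> 1      1      11      -0.417       -9.96 1.66e-06
#> 2      2      10      -0.266      -31.65 1.54e-10
#> 3      3      10       0.368       39.92 1.93e-11
#> 4      4      10       0.639       54.03 1.28e-12
#> 5      5      10       0.207       11.77 9.11e-07
```

The five discovered modules recover the five planted programs (adjusted
Rand index 0.97 against ground truth on this seed; inferred pseudotime has
Spearman correlation 0.95 with the latent truth). The projection table is
the metagene readout: advancing cells along the trajectory (Δ = +0.3)
depresses the early homeostatic module (module 1, mean log2FC −0.42) and
the transient stress module, and elevates the late translation and
inflammation modules (module 4, +0.64) — the signature an aged systemic
environment imprints on young microglia.

The image operators are exact on constructed fixtures:

```r
fx <- simulate_image_fixture(10, data.frame(cell = 1:4, area_px = 150, intensity = 10))
percent_activated(fx$label_mask, fx$puncta_image)$percent
#> [1] 40
px_area_to_um(100, 0.312)
#> [1] 31.2
```

## Command line

A thin wrapper over the same functions lives at `inst/scripts/microtraj.R`:

```sh
Rscript inst/scripts/microtraj.R run --config run.yaml --outdir out/
Rscript inst/scripts/microtraj.R simulate --outdir out/   # first stage only
Rscript inst/scripts/microtraj.R validate --config run.yaml
```

Configs are YAML (`write_run_config()` / `read_run_config()`); outputs are
plain-text tables plus a JSON manifest of seeds, parameters, and per-stage
dimensions, and runs are bit-reproducible given the same config.

## Acceptance script

`scripts/acceptance.R` re-runs the package's full computation from scratch —
generating the default synthetic aging dataset at the given seed, executing
QC → PCA → graph → trajectory → Moran screen → module discovery → a Δ = 0.3
contrast projection — and writes its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/microglia-aging-trajectories.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, the numerical choices
(tie-breaking, seeds, degenerate inputs), and known limitations.
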