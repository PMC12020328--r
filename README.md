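# nichecor

Conditional correlation of gene expression across cellular neighborhoods
in single-cell spatial transcriptomics.

## The problem

In imaging-based spatial transcriptomics (CosMx, Xenium, MERFISH), genes
expressed by the same spatially clustered cell type are automatically
correlated across space: two T-cell markers co-occur wherever T cells
aggregate. Naive spatial correlation therefore mostly rediscovers the
cell-type map. `nichecor` computes the correlation of *neighborhood*
expression **conditional on** the neighborhood cell-type composition and
technical covariates, so that what remains is spatial co-regulation the
cell-type landscape cannot explain — ligand-receptor activity, inflammation
foci, metabolic gradients — and then extracts, scores, and attributes gene
modules from it.

## The statistic

For cells $i$, genes $j$: neighborhood expression
$Y^{(N)}_{i,j} = \sum_{i' \in N(i)} Y_{i',j}$ over each cell's $k = 50$
nearest neighbors (or a fixed radius, or custom neighborhoods), and the
analogous $X^{(N)}$ for confounders (one-hot cell type, FOV, total counts,
negative-probe counts). The conditional covariance is the Schur complement

$$\mathrm{cov}(Y^{(N)} \mid X^{(N)}) = \mathrm{cov}(Y^{(N)}) -
\mathrm{cov}(Y^{(N)}, X^{(N)})\,\mathrm{cov}(X^{(N)})^{-1}\,
\mathrm{cov}(X^{(N)}, Y^{(N)}),$$

equivalently the covariance of the residuals of $Y^{(N)}$ regressed on
$X^{(N)}$; rescaled to unit diagonal it is the conditional correlation.
Estimated on a 5000-cell random subsample. Modules come from Leiden
clustering of the thresholded matrix (threshold 0.2, subclustering above 20
genes, discarding below 3 genes); module scores are weighted sums with
$w_j = \mathrm{mean}(Y^{(N)}_{\cdot,j})^{-1/2}$; cell-type attribution is
$A(j,c) = \mathrm{cor}(M^{(N)}, Y^{(N,c)}_{\cdot,j})$ with
$A(c) = \max_j A(j,c)$. Multi-sample runs summarize consensus pairs
(> 0.3 in ≥ 17/19 of samples) and inter-sample-variable pairs. See
`vignettes/conditional-spatial-correlation.Rmd` for the full account.

## Worked example

Simulate a 5000-cell tissue with 3 spatially clustered cell types and two
planted co-expression programs, then run the whole pipeline:

```r
library(nichecor)

cfg <- simulation_config(
  n_cells = 5000,
  planted_modules = list(list(affected_cell_types = "A"),
                         list(affected_cell_types = c("B", "C"))),
  seed = 99)
sim <- simulate_dataset(cfg)

res <- run_pipeline(run_config(out_dir = "demo_out", seed = 7),
                    dataset = sim$dataset)
print(res$modules)
#> module_set: 4 module(s)
#>   mod1_g3_mod1_g1: 6 genes, avg cor 0.535
#>   mod2_g5_mod2_g2: 6 genes, avg cor 0.671
#>   C_mk02_bg12: 3 genes, avg cor 0.182
#>   C_mk07_C_mk03: 3 genes, avg cor 0.166
```

Both planted 6-gene programs are recovered exactly, with strong
within-module conditional correlation (0.54, 0.67). The two trailing
3-gene modules sit just above the quality floor (`min_avg_cor = 0.1`) —
residual spatial-autocorrelation noise at this modest cell count; their low
`avg cor` is the analyst's cue to discount them, and at 10,000 cells they
disappear.

The central contrast — raw spatial correlation vs. what survives
conditioning — for two type-A marker genes and one program gene:

```r
round(res$condcor$raw_cor[c("A_mk01","A_mk02","mod1_g1"),
                          c("A_mk01","A_mk02","mod1_g1")], 2)
#>         A_mk01 A_mk02 mod1_g1
#> A_mk01    1.00   0.95    0.81
#> A_mk02    0.95   1.00    0.79
#> mod1_g1   0.81   0.79    1.00
round(res$condcor$cond_cor[c("A_mk01","A_mk02","mod1_g1"),
                           c("A_mk01","A_mk02","mod1_g1")], 2)
#>         A_mk01 A_mk02 mod1_g1
#> A_mk01    1.00  -0.08    0.08
#> A_mk02   -0.08   1.00   -0.06
#> mod1_g1   0.08  -0.06    1.00
```

The marker pair's 0.95 spatial correlation is pure cell-type geography: it
collapses to −0.08 after conditioning, while the planted program's genes
retain conditional correlations near 0.6 (see `pair_report` below).

Attribution correctly assigns the first program to cell type A:

```r
head(res$attribution$celltype_level[
  order(res$attribution$celltype_level$module,
        -res$attribution$celltype_level$score), ], 3)
#>           module cell_type      score
#>  mod1_g3_mod1_g1         A  0.9482492
#>  mod1_g3_mod1_g1         B -0.1233404
#>  mod1_g3_mod1_g1         C -0.1440502
```

Screening chosen gene pairs (the ligand-receptor use case):

```r
pair_report(res$condcor, t(combn(paste0("mod1_g", 1:3), 2)), threshold = 0.1)
#>  gene_a  gene_b  cond_cor   raw_cor pass missing
#> mod1_g1 mod1_g2 0.5828232 0.8557053 TRUE   FALSE
#> mod1_g1 mod1_g3 0.5784676 0.8599911 TRUE   FALSE
#> mod1_g2 mod1_g3 0.6178537 0.8659845 TRUE   FALSE
```

`run_pipeline()` writes `cond_cor.csv`, `raw_cor.csv`, `cor_pairs.tsv`,
`modules.tsv`, `module_edges.tsv`, `scores.csv`, `env_scores.csv`,
`attribution.csv`, `attribution_celltype.csv` and a `manifest.json`
recording the full configuration, seed, and subsample. On-disk inputs
(MatrixMarket counts + metadata CSV) are read with `load_dataset()`; a thin
CLI lives at `inst/cli/nichecor` (`run`, `simulate`, `pairs` subcommands).
Multi-sample studies go through `run_per_sample()`, `consensus_pairs()`,
and `variable_pairs()`, or `run_config(multisample = TRUE)`.

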