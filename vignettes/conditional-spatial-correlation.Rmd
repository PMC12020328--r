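---
title: "Conditional correlation of neighborhood gene expression"
author: "nichecor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional correlation of neighborhood gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecor)
```

## The problem

Imaging-based spatial transcriptomics (CosMx, Xenium, MERFISH) measures
single-cell expression together with cell positions. A natural question is
which genes are expressed in the same *places* — spatially co-regulated
programs such as ligand-receptor signaling, inflammation foci, or hypoxia
gradients. The naive approach correlates genes' expression across spatial
neighborhoods. Its fatal flaw is that most cell types are themselves
spatially organized: two T-cell markers will show near-perfect spatial
correlation simply because T cells cluster, telling the analyst nothing
beyond the cell-type map they already have.

`nichecor` measures spatial co-expression *conditional on* the cell-type
landscape and technical covariates. What survives the conditioning is
correlation that the arrangement of cell types cannot explain — the part
worth an analyst's attention.

## The model

Index cells by $i$, genes by $j$, confounders by $l$. Let $Y = \{Y_{ij}\}$ be
the (total-count-normalized) expression matrix and $X = \{X_{il}\}$ the
per-cell confounder matrix: one-hot cell-type indicators (for cell type
"T-cell", $X_{il} = 1$ iff cell $i$ is a T-cell), one-hot categorical
covariates such as FOV id, and numeric covariates such as total counts and
negative-control-probe counts.

Each cell has a neighborhood $N(i)$: its $k$ nearest cells (default
$k = 50$), all cells within a radius $r$, or a user-supplied custom
definition. Both expression and confounders are aggregated over
neighborhoods:

$$Y^{(N)}_{i,j} = \sum_{i' \in N(i)} Y_{i',j}, \qquad
  X^{(N)}_{i,l} = \sum_{i' \in N(i)} X_{i',l}.$$

The core quantity is the conditional covariance

$$\mathrm{cov}(Y^{(N)} \mid X^{(N)}) \;=\; \mathrm{cov}(Y^{(N)})
  - \mathrm{cov}(Y^{(N)}, X^{(N)})\,\mathrm{cov}(X^{(N)})^{-1}\,
    \mathrm{cov}(X^{(N)}, Y^{(N)}),$$

rescaled to unit diagonal to give the conditional correlation matrix. The
Schur complement is algebraically identical to regressing $Y^{(N)}$ on
$X^{(N)}$ (with intercept) and taking the covariance of the residuals; the
package implements both routes and its tests require them to agree to
$10^{-8}$. The residual route (QR least squares) is the default because
pivoted QR handles rank-deficient confounders — cell-type counts summing to
the neighborhood size, one-hot blocks summing to one — without an explicit
pseudo-inverse. With either route, the formula is exact for multivariate
normal data; neighborhood sums over 50 cells are approximately normal by
the central limit theorem, and we treat the Schur complement as the
*definition* of the statistic regardless of distribution.

Estimation uses a uniform random subsample of cells (default 5000),
because conditional correlations stabilize well before the full dataset is
used and the covariance computation is quadratic in genes, not cells. The
raw (unconditioned) correlation $\mathrm{cor}(Y^{(N)})$ is always computed
on the *same* subsample so the two matrices are directly comparable. No
p-values are computed: with tens of thousands of cells even trivial
correlations are "significant", so statistical significance is a
low-specificity signal here.

## From matrix to modules

The conditional correlation matrix becomes a weighted graph: entries below
a threshold (default 0.2; boundary values kept) are zeroed, the diagonal is
removed, and surviving correlations are edge weights. Because the default
threshold is positive, anti-correlated pairs never join a module — a known
limitation, not an accident. The graph is clustered with the Leiden
algorithm (modularity objective, resolution 1). Communities larger than
`max_size` (default 20 genes) are re-clustered once at double resolution;
communities smaller than `min_size` (default 3) are discarded, as are
communities whose mean off-diagonal conditional correlation falls below
`min_avg_cor` (default 0.1). Isolated genes never form modules. Modules are
named after their two most influential genes, influence being weighted
within-module degree (ties broken alphabetically, collisions suffixed).
The Leiden resolution and objective are package choices — declared, not
inherited from any reference implementation.

## Scores and attribution

Module scores are weighted sums over the module's genes, at cell level
$M_{i,m} = \sum_j w_j Y_{ij}$ and environment level
$M^{(N)}_{i,m} = \sum_j w_j Y^{(N)}_{i,j}$, with inverse-square-root
weights $w_j = \mathrm{mean}(Y^{(N)}_{\cdot,j})^{-1/2}$ to damp the
Poisson-like mean-variance relation of count data. Weights are not
renormalized to sum to one (an option exists; it changes scale only) and
are stored with the results for reproducibility.

Cell-type attribution asks which cell types *drive* a module. For module
$m$, gene $j$ and cell type $c$,
$A(j,c) = \mathrm{cor}\!\left(M^{(N)}_{\cdot,m},\, Y^{(N,c)}_{\cdot,j}\right)$,
where $Y^{(N,c)}_{i,j}$ is gene $j$'s expression summed over the type-$c$
cells in $i$'s neighborhood. The cell-type summary is
$A(c) = \max_j A(j,c)$: a type scores high if it contributes strongly to
*any* module gene. The identity $\sum_c Y^{(N,c)} = Y^{(N)}$ holds exactly
and is asserted in the tests.

## Multi-sample studies

`run_per_sample()` processes each tissue independently — its own neighbor
graph (neighborhoods never cross samples), its own subsample with seed
`master + sample index` — after skipping samples with fewer than 3000 cells,
too few to power the estimator. Two cross-sample summaries are provided:
*consensus pairs*, exceeding a correlation threshold (default 0.3) in at
least $\lceil 17/19 \cdot n \rceil$ samples, and *variable pairs*, above
`hi` in at least 3 samples and below `lo` (default 0.05) in at least 3.
The source analyses report the `hi` cutoff inconsistently (0.3 in the
methods, 0.4 in the narrative); 0.3 is the default and the cutoff is a
parameter. Genes are aligned across samples by intersection — a correlation
for an absent gene is undefined, not zero.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `knn_k` | 50 | cells | neighborhood size (KNN) |
| `radius_mm` | 0.05 | length units of coordinates | neighborhood radius |
| `include_self` | TRUE | — | cell contributes to its own neighborhood |
| `max_cells` | 5000 | cells | estimation subsample |
| `edge_threshold` | 0.2 | correlation | module graph sparsification |
| `max_module_size` | 20 | genes | triggers one re-clustering at 2x resolution |
| `min_module_size` | 3 | genes | discard floor |
| `min_avg_cor` | 0.1 | correlation | module quality floor |
| `min_counts` | 20 | counts | per-cell filter (cells below are removed) |
| `min_cells_per_sample` | 3000 | cells | multi-sample inclusion floor |

Whether the index cell belongs to its own neighborhood is genuinely
ambiguous in the field's notation; both behaviors are supported and
`include_self = TRUE` is the documented default. Aggregation is a **sum**
per the defining formula; for fixed-$k$ graphs a mean differs only by a
constant and leaves every correlation unchanged, but for radius graphs the
two differ materially, so a `mean` option exists and the sum is the
default. Neighbor-summed numeric covariates equal $k{+}1$ times the
neighborhood mean on fixed-$k$ graphs, so conditioning on "mean
neighborhood total counts" and on summed totals is the same up to an
absorbed constant.

## Numerical choices

* Rank deficiency: least-squares residualization via pivoted QR; the
  `schur` route uses a Moore-Penrose pseudo-inverse. Both are invariant to
  adding linearly dependent confounder columns (tested to $10^{-6}$).
* Genes whose conditional variance is $\le 10^{-12}$ of the mean
  conditional variance are flagged, zeroed out (diagonal included), and
  listed in `zero_variance_genes` rather than producing NaNs.
* Correlations are clamped to $[-1, 1]$ after rescaling to absorb
  floating-point overshoot.
* KNN distance ties break toward the lower cell index; all stochastic
  steps (subsampling, Leiden refinement) run under caller-supplied seeds
  with RNG state restored afterwards, so identically configured runs are
  byte-identical.
* Pearson correlation throughout; a rank-based variant was considered and
  rejected as the default because the defining formula is a covariance
  identity.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the structure the method assumes: cell
types placed in Gaussian spatial niches (plus a uniformly mixed fraction),
marker genes expressed at rate 5 in their own type and 0.05 elsewhere, a
block of housekeeping genes carrying most of each cell's counts,
log-normal per-cell depth, Poisson counts, and negative-probe counts as a
pure-noise covariate. Planted co-expression programs multiply their genes'
rates by $1 + a \cdot f_m(i)$ in affected cell types, where $f_m$ is a sum
of Gaussian bumps rescaled to $[0,1]$.

Three generator choices deserve explanation. First, housekeeping mass: a
planted program must perturb cell *totals* only mildly, as it would in a
real panel of thousands of genes; without this, total-count normalization
couples every gene to the program (compositional closure) and produces
spurious conditional correlations among bystander genes. Second, field
granularity: smooth random fields have few effective degrees of freedom,
so two programs' fields can correlate substantially by chance; successive
fields are Gram-Schmidt-orthogonalized and built from many (60) small
bumps (radius 0.12, still wider than a 50-cell neighborhood) so that
distinct planted programs are actually distinguishable ground truth.
Third, amplitude 2 with base rate 1 was calibrated once, before the
acceptance thresholds were evaluated, so that planted within-module
conditional correlations land around 0.5-0.8 — clearly above the
spatial-autocorrelation noise floor (neighborhood sums share ~$k$ cells,
cutting the effective sample size to roughly $n/(k{+}1)$) without being
trivially strong.

The simulator does **not** emulate segmentation errors, optical crowding,
FOV-edge artifacts, overdispersion beyond Poisson, or anisotropic tissue
barriers. Passing tests on these fixtures therefore demonstrates
correctness of the statistics and the pipeline, not robustness to every
artifact of real data. Neighborhoods that cross epithelial walls, for
example, will still mix compartments that the tissue separates.

## Problem sizes used in validation

The shipped validation suite runs the marker-deflation contrast on 10,000
cells (3 types, 10 markers each), planted-program recovery on 10,000 cells
(3 programs of 6 genes), and subsample stability on 20,000 cells
(5000-cell subsample vs. all cells) — sizes at which the package's
statistical behavior is already asymptotic enough to be meaningful while a
full run completes in well under a minute each on a laptop core.

## Known limitations

* Only positive conditional correlations can form modules.
* Linear conditioning removes linear cell-type effects; strongly nonlinear
  composition effects (e.g. extreme segregation combined with ratio
  normalization) can leave small residual correlations.
* 2D coordinates only; no significance testing by design; no
  Gaussian-process or spectral spatial models.
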