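#' Inverse-square-root gene weights
#'
#' Count data shows a Poisson-like mean-variance relation, so highly
#' expressed genes would dominate an unweighted module score. Weights are
#' `w_j = mean(Y^(N)[, j])^-0.5`, the inverse square root of each gene's mean
#' environment expression. Genes with zero mean environment expression are
#' excluded with a warning.
#'
#' @param env_expr Cells x genes environment expression matrix (from
#'   [environment_sum()]).
#' @param genes Gene symbols to weight (must be columns of `env_expr`).
#' @return Named numeric vector of positive weights (zero-mean genes absent).
#' @export
gene_weights <- function(env_expr, genes) {
  miss <- setdiff(genes, colnames(env_expr))
  if (length(miss)) stop("gene(s) absent from environment matrix: ",
                         paste(miss, collapse = ", "))
  mu <- colMeans(env_expr[, genes, drop = FALSE])
  zero <- mu <= 0
  if (any(zero)) {
    warning("gene(s) with zero mean environment expression excluded: ",
            paste(genes[zero], collapse = ", "))
    mu <- mu[!zero]
  }
  mu^-0.5
}

#' Per-cell and per-environment module scores
#'
#' For module `m` with weights `w_j`, the cell-level score is
#' `M[i, m] = sum_j w_j Y[i, j]` and the environment-level score is
#' `M^(N)[i, m] = sum_j w_j Y^(N)[i, j]` — weighted sums over the module's
#' genes, taken literally (set `normalize_weights = TRUE` to rescale each
#' module's weights to sum to 1, which changes scale only).
#'
#' Weights default to [gene_weights()] computed on `env_expr` and are stored
#' in the result for reproducibility.
#'
#' @param ds A [spatial_dataset()].
#' @param env_expr Environment expression matrix aligned with `ds`.
#' @param modules A `module_set`.
#' @param normalize_weights Rescale each module's weights to sum to 1.
#' @return A `score_matrix`: `cell_scores` and `env_scores` (cells x
#'   modules), and `weights_used` (per-module named vectors).
#' @export
module_scores <- function(ds, env_expr, modules, normalize_weights = FALSE) {
  stopifnot(inherits(ds, "spatial_dataset"), inherits(modules, "module_set"))
  n <- length(ds$cell_ids)
  k <- length(modules$modules)
  cell_scores <- matrix(0, n, k)
  env_scores <- matrix(0, n, k)
  weights_used <- vector("list", k)
  nm <- vapply(modules$modules, `[[`, "", "name")
  for (q in seq_len(k)) {
    m <- modules$modules[[q]]
    miss <- setdiff(m$genes, ds$gene_ids)
    if (length(miss)) stop("module gene(s) missing from dataset: ",
                           paste(miss, collapse = ", "))
    w <- m$weights
    if (all(is.na(w))) w <- gene_weights(env_expr, m$genes)
    if (normalize_weights) w <- w / sum(w)
    g <- names(w)
    cell_scores[, q] <- as.numeric(ds$counts[, g, drop = FALSE] %*% w)
    env_scores[, q] <- as.numeric(env_expr[, g, drop = FALSE] %*% w)
    weights_used[[q]] <- w
  }
  dimnames(cell_scores) <- dimnames(env_scores) <- list(ds$cell_ids, nm)
  names(weights_used) <- nm
  structure(list(cell_scores = cell_scores, env_scores = env_scores,
                 weights_used = weights_used),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d cells x %d module(s)\n",
              nrow(x$cell_scores), ncol(x$cell_scores)))
  invisible(x)
}

#' Cell-type-restricted environment expression
#'
#' `Y^(N,c)[i, j]`: the total expression of gene `j` in cells of type `c`
#' within the neighborhood of cell `i` (the index cell included per the
#' graph's `include_self` flag). Summing over all cell types recovers the
#' plain environment expression exactly.
#'
#' @param ds A [spatial_dataset()].
#' @param graph A `neighbor_graph` on the same cells.
#' @param genes Gene symbols (one or several).
#' @param cell_type A single cell-type label.
#' @param rows Optional integer subset of cells (rows of the output).
#' @return Cells x genes matrix (a vector's worth of columns per gene).
#' @export
celltype_env_expression <- function(ds, graph, genes, cell_type, rows = NULL) {
  stopifnot(inherits(ds, "spatial_dataset"), inherits(graph, "neighbor_graph"))
  if (!cell_type %in% levels(ds$cell_type))
    stop(sprintf("unknown cell type '%s'", cell_type))
  miss <- setdiff(genes, ds$gene_ids)
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  A <- neighbor_adjacency(graph)
  if (!is.null(rows)) A <- A[rows, , drop = FALSE]
  Y <- ds$counts[, genes, drop = FALSE]
  mask <- as.numeric(ds$cell_type == cell_type)
  Ym <- if (inherits(Y, "Matrix")) Matrix::Diagonal(x = mask) %*% Y else Y * mask
  out <- as.matrix(A %*% Ym)
  colnames(out) <- genes
  out
}

#' Attribute module activity to cell types
#'
#' For each module `m`, gene `j` and cell type `c`, the gene-level
#' attribution is `A(j, c) = cor(M^(N)[, m], Y^(N,c)[, j])` — the correlation
#' across cells between the module's environment score and the neighborhood
#' expression of gene `j` contributed by type-`c` cells. The cell-type-level
#' summary is `A(c) = max_j A(j, c)`, so a type scores high if it drives any
#' of the module's genes. Computed over a cell subsample (reuse the
#' conditional-correlation subsample via `rows` for paired comparisons).
#'
#' @param ds A [spatial_dataset()].
#' @param graph A `neighbor_graph`.
#' @param modules A `module_set`.
#' @param scores A `score_matrix` from [module_scores()].
#' @param max_cells,seed Subsampling parameters (used when `rows` is NULL).
#' @param rows Optional explicit integer subset of cells.
#' @return An `attribution_table`: `gene_level` data.frame (module, gene,
#'   cell_type, score) and `celltype_level` data.frame (module, cell_type,
#'   score). All scores lie in `[-1, 1]`; zero-variance vectors give 0 and
#'   are flagged in the `flat` column.
#' @export
attribution <- function(ds, graph, modules, scores,
                        max_cells = nc_defaults()$max_cells, seed = 0L,
                        rows = NULL) {
  stopifnot(inherits(modules, "module_set"), inherits(scores, "score_matrix"))
  if (is.null(rows))
    rows <- subsample_cells(length(ds$cell_ids), max_cells, seed)
  types <- levels(ds$cell_type)
  gene_rows <- list()
  ct_rows <- list()
  A <- neighbor_adjacency(graph)[rows, , drop = FALSE]
  for (m in modules$modules) {
    sc <- scores$env_scores[rows, m$name]
    sc_sd <- sd(sc)
    for (ct in types) {
      mask <- as.numeric(ds$cell_type == ct)
      Y <- ds$counts[, m$genes, drop = FALSE]
      Ym <- if (inherits(Y, "Matrix")) Matrix::Diagonal(x = mask) %*% Y else Y * mask
      env_ct <- as.matrix(A %*% Ym)
      for (q in seq_along(m$genes)) {
        v <- env_ct[, q]
        flat <- sd(v) == 0 || sc_sd == 0
        r <- if (flat) 0 else cor(sc, v)
        gene_rows[[length(gene_rows) + 1]] <- data.frame(
          module = m$name, gene = m$genes[q], cell_type = ct,
          score = r, flat = flat, stringsAsFactors = FALSE)
      }
    }
  }
  gene_level <- do.call(rbind, gene_rows)
  if (is.null(gene_level))
    gene_level <- data.frame(module = character(0), gene = character(0),
                             cell_type = character(0), score = numeric(0),
                             flat = logical(0))
  for (mn in unique(gene_level$module)) {
    sub <- gene_level[gene_level$module == mn, ]
    agg <- tapply(sub$score, sub$cell_type, max)
    ct_rows[[length(ct_rows) + 1]] <- data.frame(
      module = mn, cell_type = names(agg), score = as.numeric(agg),
      stringsAsFactors = FALSE)
  }
  celltype_level <- do.call(rbind, ct_rows)
  if (is.null(celltype_level))
    celltype_level <- data.frame(module = character(0),
                                 cell_type = character(0), score = numeric(0))
  rownames(gene_level) <- NULL
  rownames(celltype_level) <- NULL
  structure(list(gene_level = gene_level, celltype_level = celltype_level,
                 rows_used = rows),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("attribution_table: %d module(s) x %d cell type(s)\n",
              length(unique(x$celltype_level$module)),
              length(unique(x$celltype_level$cell_type))))
  invisible(x)
}
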