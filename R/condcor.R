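#' Confounder specification
#'
#' Declares which per-cell variables are treated as confounders. The cell-type
#' label expands to one-hot indicator columns; categorical covariates (e.g.
#' FOV id) likewise; numeric covariates (e.g. total counts, negative-probe
#' counts) enter as-is. All confounders are subsequently aggregated over
#' neighborhoods, exactly like expression, before conditioning.
#'
#' @param use_cell_type Include one-hot cell-type indicators.
#' @param categorical_covariates Names of categorical covariate columns.
#' @param numeric_covariates Names of numeric covariate columns.
#' @param drop_reference_level Drop the first level of each categorical block
#'   (reduces collinearity with the implicit intercept; rank deficiency is
#'   handled regardless, so the default keeps all levels).
#' @return A `confounder_spec` object.
#' @export
confounder_spec <- function(use_cell_type = TRUE,
                            categorical_covariates = character(0),
                            numeric_covariates = character(0),
                            drop_reference_level = FALSE) {
  structure(
    list(use_cell_type = isTRUE(use_cell_type),
         categorical_covariates = as.character(categorical_covariates),
         numeric_covariates = as.character(numeric_covariates),
         drop_reference_level = isTRUE(drop_reference_level)),
    class = "confounder_spec")
}

one_hot <- function(f, prefix, drop_ref) {
  f <- as.factor(f)
  lv <- levels(f)
  if (drop_ref) lv <- lv[-1]
  if (!length(lv)) {
    warning(sprintf("'%s' has a single level; empty confounder block", prefix))
    return(matrix(0, length(f), 0))
  }
  m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
  colnames(m) <- paste(prefix, lv, sep = ".")
  m
}

#' Build the per-cell confounder matrix
#'
#' Expands a [confounder_spec()] against a dataset into a cells x confounders
#' numeric matrix: one-hot cell-type columns (a cell of type "T-cell" gets 1
#' in the T-cell column and 0 elsewhere), one-hot columns per categorical
#' covariate, then numeric covariates.
#'
#' @param ds A [spatial_dataset()].
#' @param spec A [confounder_spec()].
#' @return Numeric matrix with named columns (possibly zero columns).
#' @export
build_confounder_matrix <- function(ds, spec) {
  stopifnot(inherits(ds, "spatial_dataset"), inherits(spec, "confounder_spec"))
  blocks <- list()
  if (spec$use_cell_type)
    blocks$cell_type <- one_hot(ds$cell_type, "cell_type",
                                spec$drop_reference_level)
  for (v in spec$categorical_covariates) {
    col <- confounder_column(ds, v)
    blocks[[v]] <- one_hot(col, v, spec$drop_reference_level)
  }
  if (length(spec$numeric_covariates)) {
    num <- vapply(spec$numeric_covariates,
                  function(v) as.numeric(confounder_column(ds, v)),
                  numeric(length(ds$cell_ids)))
    colnames(num) <- spec$numeric_covariates
    blocks$numeric <- num
  }
  if (!length(blocks))
    return(matrix(0, length(ds$cell_ids), 0))
  do.call(cbind, blocks)
}

confounder_column <- function(ds, v) {
  if (v == "sample" && !is.null(ds$sample_id)) return(ds$sample_id)
  if (is.null(ds$covariates) || !v %in% names(ds$covariates))
    stop(sprintf("covariate '%s' not found in dataset", v))
  ds$covariates[[v]]
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library calls do not perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw the cell subsample used for correlation estimation
#'
#' Uniform sample without replacement of `min(n_cells, max_cells)` cell
#' indices, deterministic given `seed`, returned sorted ascending. The
#' default subset size of 5000 trades precision for speed; larger subsets
#' give more precise estimates.
#'
#' @param n_cells Number of cells available.
#' @param max_cells Maximum subsample size (>= 2).
#' @param seed Integer seed.
#' @return Sorted integer vector of cell indices.
#' @export
subsample_cells <- function(n_cells, max_cells = nc_defaults()$max_cells,
                            seed = 0L) {
  if (max_cells < 2) stop("max_cells must be >= 2")
  if (n_cells <= max_cells) return(seq_len(n_cells))
  sort(with_seed(seed, sample.int(n_cells, max_cells)))
}

#' Conditional covariance of one matrix given another
#'
#' Computes `cov(Y | X) = cov(Y) - cov(Y, X) cov(X)^-1 cov(X, Y)`, the Schur
#' complement of the joint sample covariance. This equals the covariance of
#' the residuals from regressing `Y` on `X` (with intercept), which is the
#' default computational path; `method = "schur"` evaluates the Schur form
#' directly with a pseudo-inverse. Both paths tolerate rank-deficient `X`
#' (e.g. cell-type proportions summing to a constant): the projection onto
#' the column space of `X` is unique regardless.
#'
#' @param Yn Rows x genes matrix (typically environment expression over the
#'   subsample).
#' @param Xn Rows x confounders matrix over the same rows (may have zero
#'   columns, in which case `cov(Yn)` is returned).
#' @param method `"residual"` (QR least-squares residualization, default) or
#'   `"schur"` (pseudo-inverse Schur complement).
#' @return Genes x genes symmetric covariance matrix (denominator `n - 1`).
#' @export
conditional_covariance <- function(Yn, Xn = NULL,
                                   method = c("residual", "schur")) {
  method <- match.arg(method)
  Yn <- as.matrix(Yn)
  n <- nrow(Yn)
  if (n < 3) stop("need at least 3 rows")
  if (is.null(Xn)) Xn <- matrix(0, n, 0)
  Xn <- as.matrix(Xn)
  if (nrow(Xn) != n) stop("Yn and Xn must have the same number of rows")
  if (ncol(Xn) == 0) return(cov(Yn))
  if (method == "residual") {
    Yc <- scale(Yn, center = TRUE, scale = FALSE)
    Xc <- scale(Xn, center = TRUE, scale = FALSE)
    res <- qr.resid(qr(Xc), Yc)
    out <- crossprod(res) / (n - 1)
  } else {
    Syy <- cov(Yn)
    Syx <- cov(Yn, Xn)
    Sxx <- cov(Xn)
    out <- Syy - Syx %*% MASS::ginv(Sxx) %*% t(Syx)
  }
  out <- (out + t(out)) / 2
  dimnames(out) <- list(colnames(Yn), colnames(Yn))
  out
}

# Rescale a covariance to unit diagonal; genes with conditional variance at
# or below tol * mean variance are zeroed out (rows, columns, and diagonal)
# and reported in the "zero_variance" attribute.
cov_to_cor_flagged <- function(cc, tol = 1e-12) {
  d <- diag(cc)
  mv <- mean(d)
  zv <- if (mv > 0) d <= tol * mv else rep(TRUE, length(d))
  s <- sqrt(ifelse(zv, 1, d))
  corr <- cc / tcrossprod(s)
  corr[zv, ] <- 0
  corr[, zv] <- 0
  corr <- pmin(pmax(corr, -1), 1)
  diag(corr) <- ifelse(zv, 0, 1)
  attr(corr, "zero_variance") <- colnames(cc)[zv]
  corr
}

#' Conditional correlation of environment expression
#'
#' The package's primary computation. Expression and confounders are
#' aggregated over each cell's neighborhood, a random cell subsample is
#' drawn, the conditional covariance of environment expression given
#' environment confounders is computed, and the result is rescaled to unit
#' diagonal. The raw (unconditioned) correlation `cor(Y^(N))` is computed on
#' the same subsample so the two matrices are directly comparable.
#'
#' High raw spatial correlation between two genes frequently reflects
#' nothing more than the spatial clustering of the cell types expressing
#' them; conditioning on neighborhood cell-type composition (and technical
#' covariates) removes that component, leaving correlation attributable to
#' co-regulation within the cell-type landscape.
#'
#' @param ds A normalized [spatial_dataset()] (a message is emitted when raw
#'   counts are used).
#' @param graph A `neighbor_graph` built on the same cells.
#' @param spec A [confounder_spec()]; an empty spec reduces the result to the
#'   plain Pearson correlation of environment expression.
#' @param max_cells,seed Passed to [subsample_cells()].
#' @param genes Optional gene subset; restricts expression columns only (the
#'   confounders are unchanged), so results equal the corresponding submatrix
#'   of a full-panel run.
#' @param compute_raw Also compute the raw correlation matrix.
#' @param method Computational path, see [conditional_covariance()].
#' @return A `cond_cor_result` with elements `genes`, `cond_cor`, `raw_cor`,
#'   `subsample_ids`, `max_cells`, `seed`, `confounder_spec`,
#'   `zero_variance_genes`.
#' @export
conditional_correlation <- function(ds, graph, spec = confounder_spec(),
                                    max_cells = nc_defaults()$max_cells,
                                    seed = 0L, genes = NULL,
                                    compute_raw = TRUE,
                                    method = c("residual", "schur")) {
  stopifnot(inherits(ds, "spatial_dataset"), inherits(graph, "neighbor_graph"))
  method <- match.arg(method)
  if (graph$n_cells != length(ds$cell_ids))
    stop("graph was built on a different number of cells")
  if (!ds$normalized)
    message("dataset is not normalized; correlating raw environment counts")
  Y <- ds$counts
  if (!is.null(genes)) {
    genes <- as.character(genes)
    found <- intersect(genes, ds$gene_ids)
    if (!length(found)) stop("gene subset is disjoint from the panel")
    if (length(found) < length(genes))
      warning(length(genes) - length(found), " gene(s) not in panel; skipped")
    Y <- Y[, found, drop = FALSE]
  }
  X <- build_confounder_matrix(ds, spec)

  sub <- subsample_cells(graph$n_cells, max_cells, seed)
  A <- neighbor_adjacency(graph)[sub, , drop = FALSE]
  envY <- as.matrix(A %*% Y)
  colnames(envY) <- colnames(Y)
  cc <- if (ncol(X)) {
    envX <- as.matrix(A %*% X)
    conditional_covariance(envY, envX, method = method)
  } else {
    conditional_covariance(envY, NULL)
  }
  cond <- cov_to_cor_flagged(cc)
  raw <- NULL
  if (compute_raw) {
    raw <- cov_to_cor_flagged(cov(envY))
    attr(raw, "zero_variance") <- NULL
  }
  zv <- attr(cond, "zero_variance")
  attr(cond, "zero_variance") <- NULL
  structure(
    list(genes = colnames(envY), cond_cor = cond, raw_cor = raw,
         subsample_ids = ds$cell_ids[sub], max_cells = max_cells,
         seed = seed, confounder_spec = spec,
         zero_variance_genes = zv),
    class = "cond_cor_result")
}

#' @export
print.cond_cor_result <- function(x, ...) {
  cat(sprintf("cond_cor_result: %d genes, %d cells subsampled (seed %d)\n",
              length(x$genes), length(x$subsample_ids), x$seed))
  if (length(x$zero_variance_genes))
    cat("  zero conditional variance:",
        paste(x$zero_variance_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Raw spatial correlation of environment expression
#'
#' Plain Pearson correlation of the environment expression matrix over a cell
#' subsample — the unadjusted counterpart of [conditional_correlation()],
#' equal to a conditional run with an empty confounder spec.
#'
#' @inheritParams conditional_correlation
#' @return Genes x genes correlation matrix; constant genes give zero
#'   rows/columns and are listed in the `zero_variance` attribute.
#' @export
raw_correlation <- function(ds, graph, max_cells = nc_defaults()$max_cells,
                            seed = 0L, genes = NULL) {
  res <- conditional_correlation(
    ds, graph,
    spec = confounder_spec(use_cell_type = FALSE),
    max_cells = max_cells, seed = seed, genes = genes, compute_raw = FALSE)
  out <- res$cond_cor
  attr(out, "zero_variance") <- res$zero_variance_genes
  out
}
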