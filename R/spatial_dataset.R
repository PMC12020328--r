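#' Construct a spatial expression dataset
#'
#' Bundles a cells x genes count matrix with per-cell coordinates, cell-type
#' labels, optional covariates and an optional sample id into a validated
#' `spatial_dataset` object, the input to all downstream steps.
#'
#' @param counts Cells x genes matrix (dense or `Matrix` sparse), non-negative.
#'   Row names, if present, must match `cell_ids`.
#' @param positions Cells x 2 numeric matrix or data.frame of x/y coordinates,
#'   in any consistent length unit (radius parameters use the same unit).
#' @param cell_type Character or factor of per-cell cell-type labels.
#' @param covariates Optional data.frame of per-cell numeric or categorical
#'   covariates (e.g. total counts, negative-control-probe counts, FOV id).
#' @param sample_id Optional per-cell sample/tissue identifier.
#' @param cell_ids Optional character vector of unique cell identifiers;
#'   defaults to `counts` row names or `cell_1 ... cell_n`.
#' @param normalized Logical; `TRUE` if rows have already been divided by
#'   their total counts.
#' @return A `spatial_dataset` list with elements `counts`, `positions`,
#'   `cell_type`, `covariates`, `sample_id`, `cell_ids`, `gene_ids`,
#'   `library_size` (raw per-cell totals), `normalized`.
#' @export
spatial_dataset <- function(counts, positions, cell_type, covariates = NULL,
                            sample_id = NULL, cell_ids = NULL,
                            normalized = FALSE) {
  if (!inherits(counts, "Matrix")) counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  }
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (length(cell_ids) != n) stop("cell_ids length does not match counts rows")
  if (min(counts) < 0) stop("counts contain negative entries")

  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) != n || ncol(positions) != 2)
    stop("positions must be a cells x 2 matrix")
  if (!all(is.finite(positions))) stop("positions contain non-finite values")
  colnames(positions) <- c("x", "y")

  cell_type <- as.factor(cell_type)
  if (length(cell_type) != n) stop("cell_type length does not match counts rows")
  if (anyNA(cell_type)) stop("cell_type contains missing values")

  gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  dimnames(counts) <- list(cell_ids, gene_ids)

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates rows do not match counts rows")
    rownames(covariates) <- cell_ids
  }
  if (!is.null(sample_id)) {
    sample_id <- as.factor(sample_id)
    if (length(sample_id) != n) stop("sample_id length does not match counts rows")
  }
  lib <- as.numeric(Matrix::rowSums(counts))
  if (isTRUE(normalized)) {
    nz <- lib > 0
    if (any(abs(lib[nz] - 1) > 1e-9))
      stop("normalized = TRUE but rows do not sum to 1")
    lib <- rep(NA_real_, n)
  }
  structure(
    list(counts = counts, positions = positions, cell_type = cell_type,
         covariates = covariates, sample_id = sample_id,
         cell_ids = cell_ids, gene_ids = gene_ids,
         library_size = lib, normalized = isTRUE(normalized)),
    class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d cells x %d genes (%s)\n",
              length(x$cell_ids), length(x$gene_ids),
              if (x$normalized) "normalized" else "raw counts"))
  cat(sprintf("  cell types: %s\n",
              paste(levels(x$cell_type), collapse = ", ")))
  if (!is.null(x$sample_id))
    cat(sprintf("  samples: %d\n", nlevels(x$sample_id)))
  if (!is.null(x$covariates))
    cat(sprintf("  covariates: %s\n",
                paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Subset a dataset to a set of cells
#'
#' @param ds A `spatial_dataset`.
#' @param idx Integer, logical, or character (cell-id) index of cells to keep.
#' @return A `spatial_dataset` restricted to the selected cells, order
#'   following `idx`.
#' @export
subset_cells <- function(ds, idx) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.character(idx)) {
    miss <- setdiff(idx, ds$cell_ids)
    if (length(miss))
      stop("unknown cell id(s): ", paste(head(miss, 5), collapse = ", "))
    idx <- match(idx, ds$cell_ids)
  }
  if (is.logical(idx)) idx <- which(idx)
  out <- ds
  out$counts <- ds$counts[idx, , drop = FALSE]
  out$positions <- ds$positions[idx, , drop = FALSE]
  out$cell_type <- droplevels(ds$cell_type[idx])
  out$cell_ids <- ds$cell_ids[idx]
  out$library_size <- ds$library_size[idx]
  if (!is.null(ds$covariates))
    out$covariates <- droplevels(ds$covariates[idx, , drop = FALSE])
  if (!is.null(ds$sample_id)) out$sample_id <- droplevels(ds$sample_id[idx])
  out
}

#' Subset a dataset to a set of genes
#'
#' @param ds A `spatial_dataset`.
#' @param genes Character vector of gene ids (all must exist).
#' @return Dataset restricted to `genes`, in the given order. Library sizes
#'   are kept from the full panel.
#' @export
subset_genes <- function(ds, genes) {
  stopifnot(inherits(ds, "spatial_dataset"))
  miss <- setdiff(genes, ds$gene_ids)
  if (length(miss))
    stop("unknown gene(s): ", paste(head(miss, 5), collapse = ", "))
  ds$counts <- ds$counts[, genes, drop = FALSE]
  ds$gene_ids <- genes
  ds
}
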