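#' Load counts and cell metadata from disk
#'
#' Reads a cells x genes count matrix (MatrixMarket sparse triplet with
#' feature/barcode sidecars, or a dense delimited table) together with a
#' per-cell metadata table, aligns the two by cell id, and returns a
#' validated [spatial_dataset()].
#'
#' MatrixMarket input follows the 10x convention of genes as rows and cells
#' as columns; the matrix is transposed on load. Sidecar files are looked up
#' next to the matrix as `<stem>_features.tsv` / `<stem>_barcodes.tsv`, then
#' as `features.tsv` / `barcodes.tsv` in the same directory, unless given
#' explicitly. Dense input is a delimited table with gene symbols in the
#' header and cell ids in the first column.
#'
#' Cells present in only one of the two files are dropped (with a message and
#' recorded in the `dropped_cells` attribute); remaining cells follow the
#' metadata row order. Cells with missing coordinates or cell type are
#' likewise dropped and reported.
#'
#' @param counts_path Path to a `.mtx` file or a dense CSV/TSV.
#' @param metadata_path Path to the per-cell metadata CSV/TSV.
#' @param column_map Named list mapping roles to metadata column names.
#'   Recognized roles: `cell_id`, `x`, `y`, `cell_type`, `sample`, and
#'   `covariates` (character vector of additional columns to attach).
#'   Defaults: `cell_id`, `x`, `y`, `cell_type`, `sample` (attached when the
#'   column exists), covariates `total_counts` and `negprobes` when present.
#' @param features_path,barcodes_path Optional explicit sidecar paths for
#'   MatrixMarket input.
#' @return A [spatial_dataset()]; attribute `dropped_cells` lists rejected
#'   cell ids with the reason.
#' @export
load_dataset <- function(counts_path, metadata_path, column_map = list(),
                         features_path = NULL, barcodes_path = NULL) {
  cm <- utils::modifyList(
    list(cell_id = "cell_id", x = "x", y = "y", cell_type = "cell_type",
         sample = "sample", covariates = NULL),
    column_map)

  md <- read_delim_auto(metadata_path)
  for (role in c("x", "y", "cell_type")) {
    if (!cm[[role]] %in% names(md))
      stop(sprintf("metadata lacks column '%s' (role %s)", cm[[role]], role))
  }
  if (cm$cell_id %in% names(md)) {
    md_ids <- as.character(md[[cm$cell_id]])
  } else {
    md_ids <- rownames(md)
  }
  if (anyDuplicated(md_ids)) stop("duplicate cell ids in metadata")

  counts <- read_counts_matrix(counts_path, features_path, barcodes_path)
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids in counts")
  if (min(counts) < 0) stop("counts contain negative entries")

  dropped <- character(0)
  keep <- md_ids %in% rownames(counts)
  if (!any(keep)) stop("no overlap between counts and metadata cell ids")
  if (!all(keep)) {
    dropped <- c(dropped, paste0(md_ids[!keep], " [not in counts]"))
  }
  only_counts <- setdiff(rownames(counts), md_ids)
  if (length(only_counts))
    dropped <- c(dropped, paste0(only_counts, " [not in metadata]"))
  md <- md[keep, , drop = FALSE]
  md_ids <- md_ids[keep]

  bad <- !is.finite(md[[cm$x]]) | !is.finite(md[[cm$y]]) |
    is.na(md[[cm$cell_type]]) | md[[cm$cell_type]] == ""
  if (any(bad)) {
    dropped <- c(dropped, paste0(md_ids[bad], " [missing coordinate/cell type]"))
    md <- md[!bad, , drop = FALSE]
    md_ids <- md_ids[!bad]
  }
  if (length(dropped))
    message(length(dropped), " cell(s) dropped during alignment")

  counts <- counts[md_ids, , drop = FALSE]

  cov_cols <- cm$covariates
  if (is.null(cov_cols))
    cov_cols <- intersect(c("total_counts", "negprobes"), names(md))
  miss <- setdiff(cov_cols, names(md))
  if (length(miss))
    stop("covariate column(s) not in metadata: ", paste(miss, collapse = ", "))
  covs <- if (length(cov_cols)) md[, cov_cols, drop = FALSE] else NULL

  samp <- if (cm$sample %in% names(md)) md[[cm$sample]] else NULL

  ds <- spatial_dataset(
    counts = counts,
    positions = cbind(md[[cm$x]], md[[cm$y]]),
    cell_type = md[[cm$cell_type]],
    covariates = covs, sample_id = samp, cell_ids = md_ids)
  attr(ds, "dropped_cells") <- dropped
  ds
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

read_counts_matrix <- function(counts_path, features_path = NULL,
                               barcodes_path = NULL) {
  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    m <- Matrix::readMM(counts_path)
    stem <- sub("\\.mtx$", "", counts_path, ignore.case = TRUE)
    dir <- dirname(counts_path)
    pick <- function(explicit, ...) {
      if (!is.null(explicit)) return(explicit)
      for (p in c(...)) if (file.exists(p)) return(p)
      stop("sidecar file not found for ", counts_path)
    }
    fp <- pick(features_path, paste0(stem, "_features.tsv"),
               file.path(dir, "features.tsv"))
    bp <- pick(barcodes_path, paste0(stem, "_barcodes.tsv"),
               file.path(dir, "barcodes.tsv"))
    genes <- readLines(fp)
    cells <- readLines(bp)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("MTX dimensions do not match sidecar lengths")
    dimnames(m) <- list(genes, cells)
    m <- Matrix::t(m)
    as(m, "CsparseMatrix")
  } else {
    df <- read_delim_auto(counts_path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
}

#' Remove cells with low total counts
#'
#' Keeps cells whose total raw counts are at least `min_counts`; cells below
#' the threshold are removed, preserving order. The multi-sample
#' tissue-microarray recipe removes cells with fewer than 20 counts, so the
#' boundary value 20 is kept.
#'
#' @param ds A raw (non-normalized) [spatial_dataset()].
#' @param min_counts Minimum total raw counts to retain a cell.
#' @return Filtered `spatial_dataset`.
#' @export
filter_min_counts <- function(ds, min_counts = nc_defaults()$min_counts) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (ds$normalized)
    stop("filter_min_counts requires raw counts; apply before normalization")
  keep <- ds$library_size >= min_counts
  if (all(keep)) return(ds)
  subset_cells(ds, which(keep))
}

#' Normalize each cell's expression profile by its total counts
#'
#' Divides each cell's row by its raw total so rows sum to 1. Cells with zero
#' totals must be removed first (see [filter_min_counts()]). Raw totals are
#' preserved in `covariates$total_counts` for later use as a confounder.
#'
#' @param ds A raw [spatial_dataset()].
#' @return Normalized `spatial_dataset` (`normalized = TRUE`).
#' @export
normalize_total_counts <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (ds$normalized) stop("dataset is already normalized")
  tot <- ds$library_size
  if (any(tot <= 0))
    stop("cells with zero total counts present; run filter_min_counts first")
  if (inherits(ds$counts, "Matrix")) {
    ds$counts <- Matrix::Diagonal(x = 1 / tot) %*% ds$counts
    dimnames(ds$counts) <- list(ds$cell_ids, ds$gene_ids)
    ds$counts <- as(ds$counts, "CsparseMatrix")
  } else {
    ds$counts <- ds$counts / tot
  }
  if (is.null(ds$covariates)) {
    ds$covariates <- data.frame(total_counts = tot, row.names = ds$cell_ids)
  } else if (!"total_counts" %in% names(ds$covariates)) {
    ds$covariates$total_counts <- tot
  }
  ds$normalized <- TRUE
  ds
}
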