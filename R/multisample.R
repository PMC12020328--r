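#' Run conditional correlation independently per sample
#'
#' Splits a dataset by its `sample_id`, builds a fresh neighbor graph inside
#' each sample (neighborhoods never cross sample boundaries), and computes a
#' conditional correlation matrix per sample with a per-sample seed derived
#' from the master seed (`seed + sample index`). Samples with fewer cells
#' than `min_cells_per_sample` (default 3000, the minimum to power the
#' estimator on a tissue-microarray core) are skipped with a warning. All
#' samples share one gene panel, so the aligned gene set is the full panel.
#'
#' @param ds A normalized [spatial_dataset()] with `sample_id` set.
#' @param spec A [confounder_spec()].
#' @param neighborhood `"knn"` or `"radius"`.
#' @param k,r,include_self Graph parameters (see [knn_graph()],
#'   [radius_graph()]); the radius default of 0.05 matches coordinates in mm.
#' @param max_cells,seed Subsampling parameters; `seed` is the master seed.
#' @param min_cells_per_sample Minimum cells for a sample to be analyzed.
#' @return A `multi_sample_result`: `samples` (retained ids, in level order),
#'   `genes`, `per_sample_cor` (named list of `cond_cor_result`),
#'   `skipped_samples`, `seed`.
#' @export
run_per_sample <- function(ds, spec = confounder_spec(),
                           neighborhood = c("knn", "radius"),
                           k = nc_defaults()$knn_k,
                           r = nc_defaults()$radius_mm,
                           include_self = nc_defaults()$include_self,
                           max_cells = nc_defaults()$max_cells, seed = 0L,
                           min_cells_per_sample = nc_defaults()$min_cells_per_sample) {
  stopifnot(inherits(ds, "spatial_dataset"))
  neighborhood <- match.arg(neighborhood)
  if (is.null(ds$sample_id)) stop("dataset has no sample_id")
  samples <- levels(ds$sample_id)
  per <- list()
  skipped <- character(0)
  for (q in seq_along(samples)) {
    s <- samples[q]
    idx <- which(ds$sample_id == s)
    if (length(idx) < min_cells_per_sample) {
      warning(sprintf("sample '%s' skipped: %d cells < %d", s, length(idx),
                      min_cells_per_sample))
      skipped <- c(skipped, s)
      next
    }
    sub <- subset_cells(ds, idx)
    g <- if (neighborhood == "knn")
      knn_graph(sub, k = k, include_self = include_self)
    else
      radius_graph(sub, r = r, include_self = include_self)
    per[[s]] <- conditional_correlation(sub, g, spec,
                                        max_cells = max_cells,
                                        seed = seed + q)
  }
  if (!length(per)) stop("no sample retained")
  structure(list(samples = names(per), genes = ds$gene_ids,
                 per_sample_cor = per, skipped_samples = skipped,
                 seed = seed),
            class = "multi_sample_result")
}

#' @export
print.multi_sample_result <- function(x, ...) {
  cat(sprintf("multi_sample_result: %d sample(s), %d genes\n",
              length(x$samples), length(x$genes)))
  if (length(x$skipped_samples))
    cat("  skipped:", paste(x$skipped_samples, collapse = ", "), "\n")
  invisible(x)
}

pair_value_matrix <- function(result) {
  g <- result$genes
  ut <- which(upper.tri(diag(length(g))), arr.ind = TRUE)
  vals <- vapply(result$samples,
                 function(s) result$per_sample_cor[[s]]$cond_cor[ut],
                 numeric(nrow(ut)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(ut))
  list(gene_a = g[ut[, 1]], gene_b = g[ut[, 2]], values = vals)
}

#' Consensus gene pairs across samples
#'
#' Pairs whose conditional correlation strictly exceeds `cor_threshold` in at
#' least `min_samples` samples. Defaults: threshold 0.3, `min_samples =
#' ceiling(17/19 * n_samples)` — i.e. at least 17 of 19 samples at the
#' reference study size.
#'
#' @param result A `multi_sample_result`.
#' @param cor_threshold Correlation that must be exceeded.
#' @param min_samples Minimum number of samples passing.
#' @return data.frame (gene_a, gene_b, n_samples_passing), `gene_a < gene_b`,
#'   each unordered pair at most once.
#' @export
consensus_pairs <- function(result, cor_threshold = nc_defaults()$consensus_cor,
                            min_samples = NULL) {
  ns <- length(result$samples)
  if (is.null(min_samples))
    min_samples <- as.integer(ceiling(nc_defaults()$consensus_frac * ns))
  if (min_samples > ns) stop("min_samples exceeds the number of samples")
  pv <- pair_value_matrix(result)
  n_pass <- rowSums(pv$values > cor_threshold)
  keep <- which(n_pass >= min_samples)
  out <- data.frame(gene_a = pv$gene_a[keep], gene_b = pv$gene_b[keep],
                    n_samples_passing = as.integer(n_pass[keep]),
                    stringsAsFactors = FALSE)
  canonical_pairs(out)
}

#' Gene pairs with high inter-sample variability
#'
#' Pairs with conditional correlation above `hi` in at least `min_hi` samples
#' AND below `lo` in at least `min_lo` samples. Defaults `hi = 0.3`,
#' `lo = 0.05`, `min_hi = min_lo = 3`. (The reference analysis reports the
#' high cutoff as 0.3 in its methods and 0.4 in its results narrative; the
#' methods value is the default and the cutoff is a parameter.)
#'
#' @param result A `multi_sample_result`.
#' @param hi,lo Correlation cutoffs (`hi > lo`).
#' @param min_hi,min_lo Minimum sample counts above `hi` / below `lo`.
#' @return data.frame (gene_a, gene_b, n_high, n_low, then one column of
#'   per-sample values per sample), `gene_a < gene_b`.
#' @export
variable_pairs <- function(result, hi = nc_defaults()$variable_hi,
                           lo = nc_defaults()$variable_lo,
                           min_hi = nc_defaults()$variable_min_hi,
                           min_lo = nc_defaults()$variable_min_lo) {
  if (hi <= lo) stop("hi must exceed lo")
  ns <- length(result$samples)
  if (min_hi > ns || min_lo > ns)
    stop("min_hi/min_lo exceed the number of samples")
  pv <- pair_value_matrix(result)
  n_hi <- rowSums(pv$values > hi)
  n_lo <- rowSums(pv$values < lo)
  keep <- which(n_hi >= min_hi & n_lo >= min_lo)
  out <- data.frame(gene_a = pv$gene_a[keep], gene_b = pv$gene_b[keep],
                    n_high = as.integer(n_hi[keep]),
                    n_low = as.integer(n_lo[keep]),
                    stringsAsFactors = FALSE)
  vals <- pv$values[keep, , drop = FALSE]
  colnames(vals) <- result$samples
  out <- cbind(out, as.data.frame(vals))
  canonical_pairs(out)
}

canonical_pairs <- function(df) {
  if (nrow(df)) {
    swap <- df$gene_a > df$gene_b
    tmp <- df$gene_a[swap]
    df$gene_a[swap] <- df$gene_b[swap]
    df$gene_b[swap] <- tmp
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
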