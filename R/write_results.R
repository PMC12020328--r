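#' Write analysis results to disk
#'
#' Writes each result type as plain delimited text with deterministic column
#' order and float format, so identical runs produce byte-identical files.
#'
#' * `cond_cor_result`: `cond_cor.csv` and `raw_cor.csv` (gene x gene), plus
#'   `cor_pairs.tsv` in long form (gene_a, gene_b, cond_cor, raw_cor) over
#'   unordered pairs with `gene_a < gene_b`.
#' * `module_set`: `modules.tsv` (module, gene, weight) and `module_edges.tsv`
#'   (gene_a, gene_b, weight, module) when an adjacency is supplied.
#' * `score_matrix`: `scores.csv` (cells x modules, cell-level) and
#'   `env_scores.csv`.
#' * `attribution_table`: `attribution.csv` long form (module, gene,
#'   cell_type, score) and `attribution_celltype.csv`.
#' * `multi_sample_result`: `consensus_pairs.csv`, `variable_pairs.csv`, and
#'   `per_sample_cor.csv` (long form with one column per sample).
#'
#' @param result A result object of one of the classes above.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow replacing existing files.
#' @param ... Method-specific arguments (e.g. `adjacency` for module edges).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir, overwrite = FALSE, ...) {
  UseMethod("write_results")
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

nc_write_table <- function(df, path, overwrite, sep = ",") {
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  path
}

nc_write_matrix <- function(m, path, overwrite, id_col = "gene") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  nc_write_table(df, path, overwrite)
}

#' Read back a matrix written by [write_results()]
#' @param path CSV path with an id column first.
#' @return Numeric matrix with dimnames.
#' @export
read_result_matrix <- function(path) {
  df <- read.delim(path, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname write_results
#' @export
write_results.cond_cor_result <- function(result, out_dir, overwrite = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nc_write_matrix(result$cond_cor, file.path(out_dir, "cond_cor.csv"),
                    overwrite))
  if (!is.null(result$raw_cor))
    paths <- c(paths, nc_write_matrix(result$raw_cor,
                                      file.path(out_dir, "raw_cor.csv"),
                                      overwrite))
  g <- result$genes
  if (length(g) >= 2) {
    ut <- which(upper.tri(result$cond_cor), arr.ind = TRUE)
    long <- data.frame(gene_a = g[ut[, 1]], gene_b = g[ut[, 2]],
                       cond_cor = result$cond_cor[ut],
                       stringsAsFactors = FALSE)
    if (!is.null(result$raw_cor)) long$raw_cor <- result$raw_cor[ut]
    swap <- long$gene_a > long$gene_b
    tmp <- long$gene_a[swap]
    long$gene_a[swap] <- long$gene_b[swap]
    long$gene_b[swap] <- tmp
    long <- long[order(long$gene_a, long$gene_b), ]
    paths <- c(paths, nc_write_table(long, file.path(out_dir, "cor_pairs.tsv"),
                                     overwrite, sep = "\t"))
  }
  invisible(paths)
}

#' @rdname write_results
#' @export
write_results.module_set <- function(result, out_dir, overwrite = FALSE,
                                     adjacency = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(result$modules, function(m)
    data.frame(module = m$name, gene = m$genes,
               weight = as.numeric(m$weights[m$genes]),
               stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), gene = character(0),
               weight = numeric(0))
  paths <- nc_write_table(df, file.path(out_dir, "modules.tsv"), overwrite,
                          sep = "\t")
  if (!is.null(adjacency) && length(result$modules)) {
    edges <- list()
    for (m in result$modules) {
      blk <- adjacency[m$genes, m$genes, drop = FALSE]
      ut <- which(upper.tri(blk) & blk > 0, arr.ind = TRUE)
      if (nrow(ut))
        edges[[length(edges) + 1]] <- data.frame(
          gene_a = m$genes[ut[, 1]], gene_b = m$genes[ut[, 2]],
          weight = blk[ut], module = m$name, stringsAsFactors = FALSE)
    }
    edf <- if (length(edges)) do.call(rbind, edges) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 weight = numeric(0), module = character(0))
    paths <- c(paths, nc_write_table(edf,
                                     file.path(out_dir, "module_edges.tsv"),
                                     overwrite, sep = "\t"))
  }
  invisible(paths)
}

#' @rdname write_results
#' @export
write_results.score_matrix <- function(result, out_dir, overwrite = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  invisible(c(
    nc_write_matrix(result$cell_scores, file.path(out_dir, "scores.csv"),
                    overwrite, id_col = "cell_id"),
    nc_write_matrix(result$env_scores, file.path(out_dir, "env_scores.csv"),
                    overwrite, id_col = "cell_id")))
}

#' @rdname write_results
#' @export
write_results.attribution_table <- function(result, out_dir,
                                            overwrite = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gl <- result$gene_level[, c("module", "gene", "cell_type", "score")]
  invisible(c(
    nc_write_table(gl, file.path(out_dir, "attribution.csv"), overwrite),
    nc_write_table(result$celltype_level,
                   file.path(out_dir, "attribution_celltype.csv"), overwrite)))
}

#' @rdname write_results
#' @export
write_results.multi_sample_result <- function(result, out_dir,
                                              overwrite = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(result$consensus_pairs))
    paths <- c(paths, nc_write_table(
      result$consensus_pairs, file.path(out_dir, "consensus_pairs.csv"),
      overwrite))
  if (!is.null(result$variable_pairs))
    paths <- c(paths, nc_write_table(
      result$variable_pairs, file.path(out_dir, "variable_pairs.csv"),
      overwrite))
  long <- per_sample_long(result)
  paths <- c(paths, nc_write_table(long,
                                   file.path(out_dir, "per_sample_cor.csv"),
                                   overwrite))
  invisible(paths)
}

per_sample_long <- function(result) {
  g <- result$genes
  ut <- which(upper.tri(diag(length(g))), arr.ind = TRUE)
  df <- data.frame(gene_a = g[ut[, 1]], gene_b = g[ut[, 2]],
                   stringsAsFactors = FALSE)
  for (s in result$samples)
    df[[s]] <- result$per_sample_cor[[s]]$cond_cor[ut]
  df
}
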