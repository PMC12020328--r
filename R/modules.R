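#' Threshold a conditional correlation matrix into a weighted adjacency
#'
#' Entries below `threshold` are set to 0 (negative correlations are thereby
#' removed at any positive threshold); the diagonal is zeroed; surviving
#' entries keep their correlation value as edge weight. The default
#' threshold is 0.2; values equal to the threshold are kept.
#'
#' @param cond_cor Square symmetric correlation matrix.
#' @param threshold Minimum correlation for an edge.
#' @return Weighted adjacency matrix of the same dimension.
#' @export
threshold_adjacency <- function(cond_cor, threshold = nc_defaults()$edge_threshold) {
  m <- as.matrix(cond_cor)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  m[m < threshold] <- 0
  diag(m) <- 0
  m
}

#' Detect gene modules by Leiden community detection
#'
#' Clusters the thresholded conditional-correlation graph with the Leiden
#' algorithm (modularity objective, edge weights = correlations). Communities
#' larger than `max_size` are re-clustered once at double the resolution;
#' communities smaller than `min_size`, and communities whose mean
#' off-diagonal within-module conditional correlation falls below
#' `min_avg_cor`, are discarded. Degree-zero genes never form modules.
#' Deterministic given `seed`.
#'
#' @param adj Weighted adjacency from [threshold_adjacency()] (gene names as
#'   dimnames).
#' @param cond_cor Optional unthresholded conditional correlation matrix used
#'   for the average-correlation filter and stored per-module averages;
#'   defaults to `adj` (thresholded values).
#' @param resolution Leiden resolution parameter (default 1).
#' @param max_size Modules larger than this are subclustered once (default 20).
#' @param min_size Modules smaller than this are discarded (default 3).
#' @param min_avg_cor Minimum mean within-module correlation (default 0.1).
#' @param seed RNG seed for the Leiden refinement.
#' @return A `module_set`: list of modules (`name`, `genes`, `weights`
#'   placeholder filled by [module_scores()] workflows, `avg_cor`) plus the
#'   parameters used. Module genes are pairwise disjoint; names are unique,
#'   built from the two most influential genes.
#' @export
detect_modules <- function(adj, cond_cor = NULL,
                           resolution = nc_defaults()$resolution,
                           max_size = nc_defaults()$max_module_size,
                           min_size = nc_defaults()$min_module_size,
                           min_avg_cor = nc_defaults()$min_avg_cor,
                           seed = 0L) {
  adj <- as.matrix(adj)
  if (min_size < 2) stop("min_size must be >= 2")
  g_names <- colnames(adj)
  if (is.null(g_names)) g_names <- paste0("gene_", seq_len(ncol(adj)))
  if (is.null(cond_cor)) cond_cor <- adj
  params <- list(threshold = NA_real_, resolution = resolution,
                 max_size = max_size, min_size = min_size,
                 min_avg_cor = min_avg_cor, seed = seed)

  empty <- structure(list(modules = list(), params = params),
                     class = "module_set")
  deg <- rowSums(adj)
  active <- which(deg > 0)
  if (!length(active)) return(empty)

  parts <- leiden_partition(adj[active, active, drop = FALSE], resolution, seed)
  # one round of subclustering at double resolution for oversized communities
  final <- list()
  for (comm in parts) {
    if (length(comm) > max_size) {
      sub <- leiden_partition(adj[active[comm], active[comm], drop = FALSE],
                              2 * resolution, seed)
      final <- c(final, lapply(sub, function(s) active[comm[s]]))
    } else {
      final <- c(final, list(active[comm]))
    }
  }
  final <- Filter(function(v) length(v) >= min_size, final)

  mods <- list()
  for (v in final) {
    genes <- g_names[v]
    block <- cond_cor[v, v, drop = FALSE]
    avg <- mean(block[upper.tri(block)])
    if (avg < min_avg_cor) next
    mods[[length(mods) + 1]] <- list(genes = genes, avg_cor = avg,
                                     adj_block = adj[v, v, drop = FALSE])
  }
  if (!length(mods)) return(empty)
  # deterministic ordering: by size desc, then first gene
  ord <- order(-vapply(mods, function(m) length(m$genes), 1L),
               vapply(mods, function(m) m$genes[1], ""))
  mods <- mods[ord]
  used <- character(0)
  out <- lapply(mods, function(m) {
    nm <- name_module(m$genes, m$adj_block, existing = used)
    used <<- c(used, nm)
    list(name = nm, genes = m$genes,
         weights = stats::setNames(rep(NA_real_, length(m$genes)), m$genes),
         avg_cor = m$avg_cor)
  })
  structure(list(modules = out, params = params), class = "module_set")
}

# Leiden partition of a weighted adjacency; returns list of integer index
# vectors (only communities of size >= 1), deterministic given seed.
leiden_partition <- function(adj, resolution, seed) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    weights = igraph::E(g)$weight, n_iterations = 5)$membership)
  unname(split(seq_len(ncol(adj)), memb))
}

#' Name a module after its two most influential genes
#'
#' Influence is the gene's weighted degree within the module (sum of its
#' thresholded edge weights to the other module members); ties break
#' alphabetically. Name collisions get suffixes `_2`, `_3`, ...
#'
#' @param genes Module gene symbols (>= 2).
#' @param cond_cor Correlation/adjacency matrix containing those genes.
#' @param existing Already-used names, for collision suffixes.
#' @return A single string `GENE1_GENE2`.
#' @export
name_module <- function(genes, cond_cor, existing = character(0)) {
  if (length(genes) < 2) stop("a module needs at least 2 genes")
  block <- cond_cor[genes, genes, drop = FALSE]
  diag(block) <- 0
  infl <- rowSums(block)
  ord <- order(-infl, genes)
  nm <- paste(genes[ord[1:2]], collapse = "_")
  base <- nm
  q <- 2
  while (nm %in% existing) {
    nm <- paste0(base, "_", q)
    q <- q + 1
  }
  nm
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s)\n", length(x$modules)))
  for (m in x$modules)
    cat(sprintf("  %s: %d genes, avg cor %.3f\n",
                m$name, length(m$genes), m$avg_cor))
  invisible(x)
}

#' Genes assigned to any module
#' @param ms A `module_set`.
#' @return Character vector (possibly empty).
#' @export
module_genes <- function(ms) {
  unlist(lapply(ms$modules, `[[`, "genes"), use.names = FALSE)
}
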