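#' Neighbor graphs over cell positions
#'
#' A `neighbor_graph` stores, for each cell, the indices of its spatial
#' neighbors `N(i)`, plus construction metadata. Three constructors are
#' provided: k-nearest neighbors, fixed radius, and user-supplied custom
#' lists.
#'
#' @name neighbor_graph
NULL

new_neighbor_graph <- function(neighbors, method, param, include_self, n_cells) {
  structure(
    list(neighbors = neighbors, method = method, param = param,
         include_self = isTRUE(include_self), n_cells = as.integer(n_cells)),
    class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("neighbor_graph (%s, param=%s, include_self=%s): %d cells, median degree %g\n",
              x$method, format(x$param), x$include_self, x$n_cells,
              stats::median(deg)))
  invisible(x)
}

extract_positions <- function(positions) {
  if (inherits(positions, "spatial_dataset")) positions <- positions$positions
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 2) stop("positions must have two columns (x, y)")
  positions
}

#' k-nearest-neighbor graph
#'
#' Each cell's neighbors are its `k` nearest cells by Euclidean distance.
#' Distance ties are broken by lower cell index, so the graph is
#' deterministic. The default `k = 50` follows the convention of averaging
#' each cell's 50 nearest neighbors.
#'
#' @param positions Cells x 2 coordinate matrix, or a [spatial_dataset()].
#' @param k Number of neighbors (`1 <= k < n_cells`).
#' @param include_self Whether the cell itself contributes to its own
#'   neighborhood aggregate (default `TRUE`).
#' @return A `neighbor_graph`.
#' @export
knn_graph <- function(positions, k = nc_defaults()$knn_k,
                      include_self = nc_defaults()$include_self) {
  pos <- extract_positions(positions)
  n <- nrow(pos)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of cells")
  idx <- knn_brute(pos[, 1], pos[, 2], as.integer(k))
  nb <- lapply(seq_len(n), function(i) idx[i, ])
  new_neighbor_graph(nb, "knn", c(k = k), include_self, n)
}

#' Fixed-radius neighbor graph
#'
#' `N(i)` contains every other cell within Euclidean distance `r` (inclusive).
#' The relation is symmetric; cells may have empty neighborhoods.
#'
#' @inheritParams knn_graph
#' @param r Radius, in the units of the coordinates (default 0.05, intended
#'   for coordinates in mm).
#' @return A `neighbor_graph`.
#' @export
radius_graph <- function(positions, r = nc_defaults()$radius_mm,
                         include_self = nc_defaults()$include_self) {
  pos <- extract_positions(positions)
  if (r <= 0) stop("r must be positive")
  nb <- radius_brute(pos[, 1], pos[, 2], r)
  if (all(lengths(nb) == 0))
    warning("radius smaller than all pairwise distances: all neighborhoods empty")
  new_neighbor_graph(nb, "radius", c(r = r), include_self, nrow(pos))
}

#' Custom neighbor graph from user-supplied lists
#'
#' Accepts arbitrary neighborhood definitions (e.g. Delaunay, barrier-aware)
#' as a named list mapping cell id to a vector of neighbor cell ids.
#' Lists are stored verbatim (no symmetrization); duplicates within a list
#' are dropped with a warning; cells absent from the mapping get empty
#' neighborhoods.
#'
#' @param neighbor_lists Named list: cell id -> character vector of neighbor
#'   cell ids, or a two-column data.frame/matrix edge list
#'   (cell_id, neighbor_id).
#' @param ds The [spatial_dataset()] the ids refer to.
#' @param include_self As in [knn_graph()].
#' @return A `neighbor_graph` with `method = "custom"`.
#' @export
custom_graph <- function(neighbor_lists, ds,
                         include_self = nc_defaults()$include_self) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.data.frame(neighbor_lists) || is.matrix(neighbor_lists)) {
    el <- as.data.frame(neighbor_lists)
    if (ncol(el) < 2) stop("edge list must have two columns")
    neighbor_lists <- split(as.character(el[[2]]), as.character(el[[1]]))
  }
  all_ids <- unique(c(names(neighbor_lists), unlist(neighbor_lists)))
  unknown <- setdiff(all_ids, ds$cell_ids)
  if (length(unknown))
    stop("unknown cell id(s) in neighborhoods: ",
         paste(head(unknown, 5), collapse = ", "))
  n <- length(ds$cell_ids)
  nb <- rep(list(integer(0)), n)
  had_dup <- FALSE
  pos_of <- match(names(neighbor_lists), ds$cell_ids)
  for (q in seq_along(neighbor_lists)) {
    v <- match(as.character(neighbor_lists[[q]]), ds$cell_ids)
    if (anyDuplicated(v)) { had_dup <- TRUE; v <- unique(v) }
    nb[[pos_of[q]]] <- v
  }
  if (had_dup) warning("duplicate neighbors dropped")
  new_neighbor_graph(nb, "custom", NA, include_self, n)
}

#' Read a custom neighborhood edge list from a TSV file
#'
#' @param path Two-column TSV with header `cell_id`, `neighbor_id`.
#' @inheritParams custom_graph
#' @return A `neighbor_graph`.
#' @export
read_custom_graph <- function(path, ds,
                              include_self = nc_defaults()$include_self) {
  el <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  custom_graph(el, ds, include_self = include_self)
}

#' Sparse neighbor-aggregation operator
#'
#' Returns the n x n sparse 0/1 matrix `A` with `A[i, i'] = 1` for
#' `i' %in% N(i)` (plus the diagonal when `include_self`), so that
#' `A %*% mat` is the neighborhood sum of any per-cell matrix.
#'
#' @param graph A `neighbor_graph`.
#' @return A `dgCMatrix`.
#' @export
neighbor_adjacency <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- graph$n_cells
  deg <- lengths(graph$neighbors)
  i <- rep.int(seq_len(n), deg)
  j <- unlist(graph$neighbors, use.names = FALSE)
  if (graph$include_self) {
    i <- c(i, seq_len(n))
    j <- c(j, seq_len(n))
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

#' Aggregate a per-cell matrix over neighborhoods
#'
#' Computes the environment matrix `M^(N)` with
#' `M^(N)[i, j] = sum over i' in N(i) of M[i', j]` (the cell's own row is
#' added when the graph was built with `include_self = TRUE`). Applied to
#' expression this yields the environment expression matrix; applied to
#' confounders, the environment confounder matrix.
#'
#' @param graph A `neighbor_graph`.
#' @param mat Cells x features matrix (dense or sparse); rows must match
#'   `graph$n_cells`.
#' @param mean Divide each row by its neighborhood size (sum -> mean).
#' @return Dense matrix of the same shape as `mat`, with attribute
#'   `graph_fingerprint` identifying the graph used.
#' @export
environment_sum <- function(graph, mat, mean = FALSE) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (nrow(mat) != graph$n_cells)
    stop("matrix rows do not match graph n_cells")
  A <- neighbor_adjacency(graph)
  out <- as.matrix(A %*% mat)
  if (mean) {
    sz <- lengths(graph$neighbors) + as.integer(graph$include_self)
    out <- out / pmax(sz, 1)
  }
  rownames(out) <- rownames(mat)
  colnames(out) <- colnames(mat)
  attr(out, "graph_fingerprint") <- graph_fingerprint(graph)
  out
}

graph_fingerprint <- function(graph) {
  key <- c(graph$method, format(graph$param), graph$include_self,
           graph$n_cells, sum(lengths(graph$neighbors)),
           sum(as.numeric(unlist(graph$neighbors, use.names = FALSE))))
  paste(key, collapse = "|")
}
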