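#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline into one validated
#' object. All defaults come from [nc_defaults()] and are echoed into the
#' run manifest, so a manifest fully documents a run.
#'
#' @param counts,metadata Input paths (see [load_dataset()]); may be `NULL`
#'   when a dataset object is passed to [run_pipeline()] directly.
#' @param out_dir Output directory.
#' @param column_map Passed to [load_dataset()].
#' @param neighborhood List: `method` ("knn", "radius" or "custom"), `k`,
#'   `r`, `include_self`, and for "custom" a `path` to an edge-list TSV.
#' @param confounders A [confounder_spec()], or `NULL` to condition on cell
#'   type plus whichever of `total_counts` / `negprobes` covariates exist.
#' @param max_cells Subsample size for correlation estimation.
#' @param edge_threshold,max_module_size,min_module_size,min_avg_cor,resolution
#'   Module-detection tunables (see [threshold_adjacency()],
#'   [detect_modules()]).
#' @param min_counts Per-cell count filter applied before normalization;
#'   `NULL` disables it (the tissue-microarray recipe uses 20).
#' @param normalize Divide each cell's profile by its total counts.
#' @param gene_subset Path to a one-symbol-per-line file, or a character
#'   vector: restrict the correlation to these genes (confounders unchanged).
#' @param cell_subset Name of a logical metadata/covariate column; cells
#'   where it is `TRUE` are kept, and the filter is applied before graph
#'   construction so neighborhoods stay inside the region.
#' @param multisample Run per-sample and summarize consensus/variable pairs
#'   (requires a sample column); see [run_per_sample()].
#' @param min_cells_per_sample,consensus_cor,variable_hi,variable_lo
#'   Multi-sample tunables.
#' @param seed Master seed for subsampling and community detection.
#' @param overwrite Allow replacing existing output files.
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, metadata = NULL, out_dir = NULL,
                       column_map = list(),
                       neighborhood = list(), confounders = NULL,
                       max_cells = nc_defaults()$max_cells,
                       edge_threshold = nc_defaults()$edge_threshold,
                       max_module_size = nc_defaults()$max_module_size,
                       min_module_size = nc_defaults()$min_module_size,
                       min_avg_cor = nc_defaults()$min_avg_cor,
                       resolution = nc_defaults()$resolution,
                       min_counts = NULL, normalize = TRUE,
                       gene_subset = NULL, cell_subset = NULL,
                       multisample = FALSE,
                       min_cells_per_sample = nc_defaults()$min_cells_per_sample,
                       consensus_cor = nc_defaults()$consensus_cor,
                       variable_hi = nc_defaults()$variable_hi,
                       variable_lo = nc_defaults()$variable_lo,
                       seed = 0L, overwrite = FALSE) {
  nb <- utils::modifyList(
    list(method = "knn", k = nc_defaults()$knn_k,
         r = nc_defaults()$radius_mm,
         include_self = nc_defaults()$include_self, path = NULL),
    neighborhood)
  if (!nb$method %in% c("knn", "radius", "custom"))
    stop("neighborhood method must be knn, radius or custom")
  structure(
    list(counts = counts, metadata = metadata, out_dir = out_dir,
         column_map = column_map, neighborhood = nb,
         confounders = confounders, max_cells = max_cells,
         edge_threshold = edge_threshold,
         max_module_size = max_module_size,
         min_module_size = min_module_size, min_avg_cor = min_avg_cor,
         resolution = resolution, min_counts = min_counts,
         normalize = isTRUE(normalize), gene_subset = gene_subset,
         cell_subset = cell_subset, multisample = isTRUE(multisample),
         min_cells_per_sample = min_cells_per_sample,
         consensus_cor = consensus_cor, variable_hi = variable_hi,
         variable_lo = variable_lo,
         seed = as.integer(seed), overwrite = isTRUE(overwrite)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; the `confounders` block maps
#' to [confounder_spec()] fields. Round-trips losslessly: unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$confounders))
    y$confounders <- do.call(confounder_spec, y$confounders)
  do.call(run_config, y)
}

default_confounders <- function(ds) {
  have <- if (is.null(ds$covariates)) character(0) else names(ds$covariates)
  confounder_spec(
    use_cell_type = TRUE,
    numeric_covariates = intersect(c("total_counts", "negprobes"), have))
}

build_graph_from_config <- function(ds, nb) {
  switch(nb$method,
         knn = knn_graph(ds, k = nb$k, include_self = nb$include_self),
         radius = radius_graph(ds, r = nb$r, include_self = nb$include_self),
         custom = read_custom_graph(nb$path, ds,
                                    include_self = nb$include_self))
}

#' Run the full pipeline
#'
#' Executes load -> filter/normalize -> neighbor graph -> conditional + raw
#' correlation -> module detection -> weights/scores -> cell-type attribution
#' -> writers, and writes a JSON run manifest (config echo, seed, subsample
#' ids, stage timings and dimensions, package version). Any stage error
#' aborts with the stage name. In multisample mode the per-sample workflow
#' and consensus/variable pair summaries replace the module stages.
#'
#' @param cfg A [run_config()].
#' @param dataset Optional in-memory [spatial_dataset()]; skips the load
#'   stage (input paths in `cfg` are then ignored).
#' @return Invisibly, a list with the intermediate objects (`dataset`,
#'   `graph`, `condcor`, `modules`, `scores`, `attribution` or
#'   `multisample`), the output `paths`, and the `manifest`.
#' @export
run_pipeline <- function(cfg, dataset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out_dir)) stop("config lacks out_dir")
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(stage, note) {
    stages[[stage]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
                             note = note)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  ds <- run_stage("load", {
    if (is.null(dataset)) {
      if (is.null(cfg$counts) || is.null(cfg$metadata))
        stop("no dataset given and no input paths configured")
      load_dataset(cfg$counts, cfg$metadata, cfg$column_map)
    } else dataset
  })
  tick("load", sprintf("%d cells x %d genes", nrow(ds$counts), ncol(ds$counts)))

  ds <- run_stage("filter", {
    if (!is.null(cfg$cell_subset)) {
      col <- confounder_column(ds, cfg$cell_subset)
      ds <- subset_cells(ds, which(as.logical(col)))
    }
    if (!is.null(cfg$min_counts) && !ds$normalized)
      ds <- filter_min_counts(ds, cfg$min_counts)
    ds
  })
  tick("filter", sprintf("%d cells retained", nrow(ds$counts)))

  ds <- run_stage("normalize",
                  if (cfg$normalize && !ds$normalized)
                    normalize_total_counts(ds) else ds)
  tick("normalize", if (ds$normalized) "row-sum normalized" else "raw counts")

  spec <- if (is.null(cfg$confounders)) default_confounders(ds) else
    cfg$confounders

  genes <- cfg$gene_subset
  if (is.character(genes) && length(genes) == 1 && file.exists(genes))
    genes <- readLines(genes)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  out <- list(dataset = ds)

  if (cfg$multisample) {
    ms <- run_stage("multisample", {
      res <- run_per_sample(ds, spec,
                            neighborhood = if (cfg$neighborhood$method == "radius")
                              "radius" else "knn",
                            k = cfg$neighborhood$k, r = cfg$neighborhood$r,
                            include_self = cfg$neighborhood$include_self,
                            max_cells = cfg$max_cells, seed = cfg$seed,
                            min_cells_per_sample = cfg$min_cells_per_sample)
      res$consensus_pairs <- consensus_pairs(res, cfg$consensus_cor)
      res$variable_pairs <- variable_pairs(res, hi = cfg$variable_hi,
                                           lo = cfg$variable_lo)
      res
    })
    tick("multisample", sprintf("%d sample(s)", length(ms$samples)))
    paths <- c(paths, write_results(ms, cfg$out_dir,
                                    overwrite = cfg$overwrite))
    out$multisample <- ms
  } else {
    graph <- run_stage("graph", build_graph_from_config(ds, cfg$neighborhood))
    tick("graph", sprintf("%s graph on %d cells", graph$method,
                          graph$n_cells))
    cc <- run_stage("condcor",
                    conditional_correlation(ds, graph, spec,
                                            max_cells = cfg$max_cells,
                                            seed = cfg$seed, genes = genes))
    tick("condcor", sprintf("%d genes, %d cells subsampled",
                            length(cc$genes), length(cc$subsample_ids)))
    adj <- threshold_adjacency(cc$cond_cor, cfg$edge_threshold)
    modules <- run_stage("modules",
                         detect_modules(adj, cond_cor = cc$cond_cor,
                                        resolution = cfg$resolution,
                                        max_size = cfg$max_module_size,
                                        min_size = cfg$min_module_size,
                                        min_avg_cor = cfg$min_avg_cor,
                                        seed = cfg$seed))
    modules$params$threshold <- cfg$edge_threshold
    tick("modules", sprintf("%d module(s)", length(modules$modules)))

    env_expr <- run_stage("scores_env",
                          environment_sum(graph, ds$counts[, cc$genes,
                                                           drop = FALSE]))
    scores <- run_stage("scores", module_scores(ds, env_expr, modules))
    for (q in seq_along(modules$modules)) {
      w <- scores$weights_used[[modules$modules[[q]]$name]]
      modules$modules[[q]]$weights[names(w)] <- w
    }
    tick("scores", sprintf("%d module(s) scored", ncol(scores$cell_scores)))
    rows <- match(cc$subsample_ids, ds$cell_ids)
    attrib <- run_stage("attribution",
                        attribution(ds, graph, modules, scores, rows = rows))
    tick("attribution", sprintf("%d rows", nrow(attrib$gene_level)))

    paths <- c(paths,
               write_results(cc, cfg$out_dir, overwrite = cfg$overwrite),
               write_results(modules, cfg$out_dir, overwrite = cfg$overwrite,
                             adjacency = adj),
               write_results(scores, cfg$out_dir, overwrite = cfg$overwrite),
               write_results(attrib, cfg$out_dir, overwrite = cfg$overwrite))
    paths <- c(paths, write_fov_summary(ds, scores, cfg))
    out <- c(out, list(graph = graph, condcor = cc, modules = modules,
                       scores = scores, attribution = attrib))
  }

  manifest <- list(
    package = "nichecor",
    version = as.character(utils::packageVersion("nichecor")),
    seed = cfg$seed,
    config = config_echo(cfg),
    n_cells = nrow(ds$counts), n_genes = ncol(ds$counts),
    subsample_ids = if (!cfg$multisample) out$condcor$subsample_ids else NULL,
    stages = stages)
  mpath <- file.path(cfg$out_dir, "manifest.json")
  if (file.exists(mpath) && !cfg$overwrite)
    stop("file exists (use overwrite = TRUE): ", mpath)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  out$paths <- c(paths, mpath)
  out$manifest <- manifest
  invisible(out)
}

config_echo <- function(cfg) {
  e <- unclass(cfg)
  if (!is.null(e$confounders)) e$confounders <- unclass(e$confounders)
  e
}

# Per-FOV mean module scores, written when a "fov" covariate exists: a
# module driven by a single outlying FOV shows up directly in this table.
write_fov_summary <- function(ds, scores, cfg) {
  if (is.null(ds$covariates) || !"fov" %in% names(ds$covariates))
    return(character(0))
  if (!ncol(scores$cell_scores)) return(character(0))
  fov <- as.factor(ds$covariates$fov)
  agg <- apply(scores$cell_scores, 2, function(v) tapply(v, fov, mean))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = nlevels(fov),
                                       dimnames = list(levels(fov),
                                                       colnames(scores$cell_scores)))
  nc_write_matrix(agg, file.path(cfg$out_dir, "fov_score_summary.csv"),
                  cfg$overwrite, id_col = "fov")
}

#' Report conditional and raw correlation for chosen gene pairs
#'
#' A screening utility for curated pair lists (e.g. ligand-receptor pairs):
#' for each unordered pair, reports the conditional and raw correlation and
#' whether the conditional value passes `threshold`. Pairs naming unknown
#' genes are kept in the table with `missing = TRUE` rather than failing.
#'
#' @param result A `cond_cor_result`.
#' @param pairs Two-column data.frame/matrix of gene symbols.
#' @param threshold Pass/fail cutoff on conditional correlation.
#' @return data.frame (gene_a, gene_b, cond_cor, raw_cor, pass, missing);
#'   duplicated unordered pairs are reported once. Attribute `n_pass` gives
#'   the number of passing pairs.
#' @export
pair_report <- function(result, pairs, threshold = 0.1) {
  stopifnot(inherits(result, "cond_cor_result"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      cond_cor = numeric(0), raw_cor = numeric(0),
                      pass = logical(0), missing = logical(0))
    attr(out, "n_pass") <- 0L
    return(out)
  }
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(paste(a, b, sep = "|"))
  a <- a[keep]; b <- b[keep]
  known <- a %in% result$genes & b %in% result$genes
  cc <- rep(NA_real_, length(a))
  rc <- rep(NA_real_, length(a))
  cc[known] <- result$cond_cor[cbind(a[known], b[known])]
  if (!is.null(result$raw_cor))
    rc[known] <- result$raw_cor[cbind(a[known], b[known])]
  out <- data.frame(gene_a = a, gene_b = b, cond_cor = cc, raw_cor = rc,
                    pass = !is.na(cc) & cc > threshold, missing = !known,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  attr(out, "n_pass") <- sum(out$pass)
  out
}
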