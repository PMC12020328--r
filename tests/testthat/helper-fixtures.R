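# Shared fixtures, built in code. Small simulations are cached per session
# so several test files can reuse them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 6 cells on a line, 4 genes, 2 cell types, fully deterministic counts.
tiny_dataset <- function() {
  counts <- matrix(c(
    4, 0, 1, 0,
    2, 2, 0, 1,
    0, 5, 1, 0,
    1, 1, 3, 0,
    0, 0, 2, 4,
    3, 1, 0, 2), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("c", 1:6), c("gA", "gB", "gC", "gD")))
  spatial_dataset(
    counts = counts,
    positions = cbind(x = as.numeric(1:6), y = rep(0, 6)),
    cell_type = c("T", "T", "B", "B", "T", "B"),
    covariates = data.frame(negprobes = c(1, 0, 2, 1, 0, 1)))
}

# Small spatially structured simulation with one planted module.
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- simulation_config(
      n_cells = 1500,
      planted_modules = list(list(affected_cell_types = "A")),
      seed = 421)
    simulate_dataset(cfg)
  })
}

# Normalized version plus a k-NN graph, reused by several files.
small_pipeline_inputs <- function() {
  cached("small_pipeline_inputs", function() {
    sim <- small_sim()
    ds <- normalize_total_counts(sim$dataset)
    graph <- knn_graph(ds, k = 30)
    list(sim = sim, ds = ds, graph = graph,
         spec = confounder_spec(numeric_covariates = c("total_counts",
                                                       "negprobes")))
  })
}

# Assemble a multi_sample_result from hand-built correlation matrices.
fake_multisample <- function(mats) {
  genes <- rownames(mats[[1]])
  samples <- paste0("s", seq_along(mats))
  per <- lapply(seq_along(mats), function(q)
    structure(list(genes = genes, cond_cor = mats[[q]], raw_cor = NULL,
                   subsample_ids = character(0), max_cells = 0L,
                   seed = q, confounder_spec = confounder_spec(),
                   zero_variance_genes = character(0)),
              class = "cond_cor_result"))
  names(per) <- samples
  structure(list(samples = samples, genes = genes, per_sample_cor = per,
                 skipped_samples = character(0), seed = 0L),
            class = "multi_sample_result")
}

# Symmetric matrix with unit diagonal from a vector of upper-triangle values.
sym_from_upper <- function(genes, values) {
  p <- length(genes)
  m <- diag(p)
  m[upper.tri(m)] <- values
  m <- m + t(m) - diag(p)
  dimnames(m) <- list(genes, genes)
  m
}
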