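test_that("gene weights are inverse square roots of mean environment expression", {
  env <- cbind(g1 = rep(1, 10), g2 = rep(4, 10), g3 = rep(0, 10))
  expect_equal(gene_weights(env, "g1"), c(g1 = 1))
  expect_equal(gene_weights(env, "g2"), c(g2 = 0.5))
  expect_warning(w <- gene_weights(env, c("g1", "g3")), "zero mean")
  expect_identical(names(w), "g1")
  set.seed(51)
  env2 <- matrix(rexp(600) + 0.1, 100, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  expect_equal(gene_weights(env2, colnames(env2)),
               colMeans(env2)^-0.5, tolerance = 1e-12)
  expect_error(gene_weights(env2, "missing"), "absent")
})

make_module_set <- function(mods) {
  structure(list(modules = mods,
                 params = list(threshold = 0.2, resolution = 1,
                               max_size = 20, min_size = 2,
                               min_avg_cor = 0, seed = 0)),
            class = "module_set")
}

test_that("module scores are weighted sums at cell and environment level", {
  ds <- tiny_dataset()
  g <- knn_graph(ds, k = 2, include_self = TRUE)
  env <- environment_sum(g, ds$counts)
  # fixed weights: score = 0.5 * gA + 1.0 * gB
  ms <- make_module_set(list(list(
    name = "gA_gB", genes = c("gA", "gB"),
    weights = c(gA = 0.5, gB = 1.0), avg_cor = 1)))
  sc <- module_scores(ds, env, ms)
  expect_equal(unname(sc$cell_scores[, 1]),
               unname(0.5 * as.matrix(ds$counts)[, "gA"] +
                      as.matrix(ds$counts)[, "gB"]))
  expect_equal(unname(sc$env_scores[, 1]),
               unname(0.5 * env[, "gA"] + env[, "gB"]))
  # a cell with expression (4, 3) and weights (0.5, 1) scores 5
  expect_equal(unname(sc$cell_scores["c3", 1]), 5)
  # single-gene module with weight 1 reproduces the expression column
  one <- make_module_set(list(list(name = "gC", genes = "gC",
                                   weights = c(gC = 1), avg_cor = 1)))
  expect_equal(unname(module_scores(ds, env, one)$cell_scores[, 1]),
               unname(as.matrix(ds$counts)[, "gC"]))
  # linearity: doubling expression doubles both score types
  ds2 <- spatial_dataset(2 * as.matrix(ds$counts), ds$positions, ds$cell_type)
  sc2 <- module_scores(ds2, environment_sum(g, ds2$counts), ms)
  expect_equal(sc2$cell_scores, 2 * sc$cell_scores)
  expect_equal(sc2$env_scores, 2 * sc$env_scores)
  # normalized weights change scale only
  scn <- module_scores(ds, env, ms, normalize_weights = TRUE)
  expect_equal(scn$cell_scores[, 1] * 1.5, sc$cell_scores[, 1])
  bad <- make_module_set(list(list(name = "zz", genes = "zz",
                                   weights = c(zz = 1), avg_cor = 1)))
  expect_error(module_scores(ds, env, bad), "zz")
})

test_that("cell-type-restricted environment expression sums by mask", {
  ds <- tiny_dataset()
  g <- custom_graph(list(c1 = c("c2", "c3"), c2 = c("c1", "c4"),
                         c3 = "c4", c4 = "c3"), ds, include_self = FALSE)
  # hand enumeration for gene gA, type T (cells c1, c2, c5)
  got <- celltype_env_expression(ds, g, "gA", "T")
  counts <- as.matrix(ds$counts)
  expect_equal(unname(got[1:4, 1]),
               c(counts["c2", "gA"], counts["c1", "gA"], 0, 0))
  # partition identity: summing over all types recovers the environment sum
  env <- environment_sum(g, ds$counts)
  total <- Reduce(`+`, lapply(levels(ds$cell_type), function(tp)
    celltype_env_expression(ds, g, ds$gene_ids, tp)))
  expect_equal(unname(total), unname(env), ignore_attr = TRUE)
  # single-type dataset: equals the plain environment column
  one <- spatial_dataset(counts, ds$positions, rep("T", 6))
  g1 <- knn_graph(one, k = 2)
  expect_equal(unname(celltype_env_expression(one, g1, "gB", "T")[, 1]),
               unname(environment_sum(g1, one$counts)[, "gB"]))
  expect_error(celltype_env_expression(ds, g, "gA", "nope"), "unknown")
})

test_that("attribution ranks the expressing cell type first", {
  set.seed(52)
  n <- 200
  pos <- cbind(runif(n), runif(n))
  type <- rep(c("A", "B"), each = n / 2)
  # two genes expressed only by type A, spatially co-varying via a gradient
  grad <- 1 + 3 * pos[, 1]
  counts <- cbind(
    m1 = rpois(n, ifelse(type == "A", 5 * grad, 0.01)),
    m2 = rpois(n, ifelse(type == "A", 4 * grad, 0.01)),
    other = rpois(n, 2))
  ds <- spatial_dataset(counts, pos, type)
  g <- knn_graph(ds, k = 15)
  env <- environment_sum(g, ds$counts)
  ms <- make_module_set(list(list(
    name = "m1_m2", genes = c("m1", "m2"),
    weights = gene_weights(env, c("m1", "m2")), avg_cor = 1)))
  sc <- module_scores(ds, env, ms)
  at <- attribution(ds, g, ms, sc, max_cells = n, seed = 1)
  ct <- at$celltype_level
  expect_gt(ct$score[ct$cell_type == "A"], ct$score[ct$cell_type == "B"])
  expect_true(all(abs(at$gene_level$score) <= 1))
  # celltype level is the exact max over the module's gene-level entries
  for (tp in c("A", "B")) {
    gl <- at$gene_level[at$gene_level$cell_type == tp, ]
    expect_equal(ct$score[ct$cell_type == tp], max(gl$score))
  }
  # loop-based oracle for one entry
  rows <- at$rows_used
  A <- neighbor_adjacency(g)
  envA_m1 <- vapply(seq_len(n), function(i) {
    nb <- c(i, g$neighbors[[i]])
    sum(counts[nb, "m1"][type[nb] == "A"])
  }, 1)
  oracle <- cor(sc$env_scores[rows, 1], envA_m1[rows])
  got <- at$gene_level
  expect_equal(got$score[got$gene == "m1" & got$cell_type == "A"], oracle)
})

test_that("single-type attribution reduces to plain correlation", {
  inp <- small_pipeline_inputs()
  ds <- inp$ds
  one <- spatial_dataset(as.matrix(ds$counts), ds$positions,
                         rep("X", nrow(ds$counts)))
  g <- inp$graph
  env <- environment_sum(g, one$counts)
  ms <- make_module_set(list(list(
    name = "mod1_g1_mod1_g2", genes = c("mod1_g1", "mod1_g2"),
    weights = gene_weights(env, c("mod1_g1", "mod1_g2")), avg_cor = 1)))
  sc <- module_scores(one, env, ms)
  at <- attribution(one, g, ms, sc, max_cells = 400, seed = 3)
  rows <- at$rows_used
  gl <- at$gene_level
  expect_equal(gl$score[gl$gene == "mod1_g1"],
               cor(sc$env_scores[rows, 1], env[rows, "mod1_g1"]))
})
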