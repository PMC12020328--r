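test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_cells = 300, seed = 9,
                           planted_modules = list(list()))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$dataset$counts), as.matrix(b$dataset$counts))
  expect_identical(a$dataset$positions, b$dataset$positions)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_dataset(simulation_config(n_cells = 300, seed = 10,
                                           planted_modules = list(list())))
  expect_false(identical(as.matrix(a$dataset$counts),
                         as.matrix(c2$dataset$counts)))
})

test_that("truth bookkeeping is consistent with the emitted dataset", {
  sim <- small_sim()
  expect_identical(names(sim$truth$module_membership), sim$dataset$gene_ids)
  expect_identical(sim$truth$type_assignments,
                   as.character(sim$dataset$cell_type))
  mem <- sim$truth$module_membership
  expect_setequal(names(mem)[!is.na(mem)], paste0("mod1_g", 1:6))
  expect_equal(nrow(sim$truth$latent_field_values), nrow(sim$dataset$counts))
  expect_true(all(sim$dataset$positions[, 1] >= 0 &
                  sim$dataset$positions[, 1] <= 2))
})

test_that("expected totals scale linearly with the depth size factor", {
  sim <- cached("depth_sim", function()
    simulate_dataset(simulation_config(n_cells = 10000, seed = 13)))
  tot <- rowSums(as.matrix(sim$dataset$counts))
  fit <- lm(tot ~ sim$truth$depth)
  base <- mean(tot / sim$truth$depth)
  # slope ~ mean expression mass, intercept ~ 0 relative to it
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_lt(abs(coef(fit)[1]) / base, 0.1)
})

test_that("a structureless simulation yields near-null conditional correlation", {
  cfg <- simulation_config(n_cells = 3000, n_cell_types = 1,
                           depth_sdlog = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  ds <- normalize_total_counts(sim$dataset)
  g <- knn_graph(ds, k = 50)
  res <- conditional_correlation(ds, g,
                                 confounder_spec(numeric_covariates =
                                                   "total_counts"),
                                 seed = 2)
  off <- abs(res$cond_cor[upper.tri(res$cond_cor)])
  # neighborhood sums share ~k+1 cells, cutting the effective sample size to
  # about n/(k+1); the null bound is two such standard errors
  bound <- 2 / sqrt(nrow(ds$counts) / 51)
  expect_gt(mean(off < bound), 0.95)
})

test_that("marker pairs correlate spatially but not conditionally", {
  inp <- small_pipeline_inputs()
  res <- conditional_correlation(inp$ds, inp$graph, inp$spec,
                                 max_cells = 1500, seed = 3)
  same_type <- function(m) {
    unlist(lapply(c("A_mk", "B_mk", "C_mk"), function(p) {
      b <- m[grep(p, rownames(m)), grep(p, colnames(m))]
      b[upper.tri(b)]
    }))
  }
  expect_gt(median(same_type(res$raw_cor)), 0.5)
  expect_gt(median(same_type(res$raw_cor)), median(abs(same_type(res$cond_cor))))
})

test_that("recovery metrics follow the combinatorial definitions", {
  truth <- structure(
    list(module_membership = stats::setNames(
      c(rep("m1", 6), NA, NA),
      c(paste0("g", 1:6), "x1", "x2"))),
    class = "synthetic_truth")
  mkset <- function(groups) {
    structure(list(modules = lapply(seq_along(groups), function(q)
      list(name = paste0("M", q), genes = groups[[q]],
           weights = stats::setNames(rep(1, length(groups[[q]])),
                                     groups[[q]]),
           avg_cor = 1)),
      params = list()), class = "module_set")
  }
  # perfect recovery
  ev <- evaluate_recovery(mkset(list(paste0("g", 1:6))), truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$ari, 1)
  # empty recovery: flagged, reported as zero
  ev0 <- evaluate_recovery(mkset(list()), truth)
  expect_false(ev0$precision_defined)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  # 6-gene module split into two 3-gene halves: recall = 6/15
  ev2 <- evaluate_recovery(mkset(list(paste0("g", 1:3), paste0("g", 4:6))),
                           truth)
  expect_equal(ev2$recall, 6 / 15)
  expect_equal(ev2$precision, 1)
  # an off-truth gene in a module costs precision only
  ev3 <- evaluate_recovery(mkset(list(c(paste0("g", 1:6), "x1"))), truth)
  expect_equal(ev3$recall, 1)
  expect_equal(ev3$precision, 15 / 21)
})

test_that("exported simulations reload identically through data_io", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  export_simulation(sim, dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(names(truth$module_membership), paste0("mod1_g", 1:6))
  ds <- load_dataset(file.path(dir, "counts.mtx"),
                     file.path(dir, "metadata.csv"))
  expect_equal(as.matrix(ds$counts), as.matrix(sim$dataset$counts),
               ignore_attr = TRUE)
})
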