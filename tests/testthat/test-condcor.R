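test_that("confounder matrix one-hot encodes cell types and covariates", {
  ds <- spatial_dataset(matrix(1, 5, 2), cbind(1:5, 0),
                        c("T-cell", "B", "T-cell", "B", "B"),
                        covariates = data.frame(tot = c(5, 2, 7, 1, 3)))
  X <- build_confounder_matrix(ds, confounder_spec())
  expect_equal(unname(X[, "cell_type.T-cell"]), c(1, 0, 1, 0, 0))
  expect_equal(unname(X[, "cell_type.B"]), c(0, 1, 0, 1, 0) + c(0, 0, 0, 0, 1))
  expect_equal(unname(rowSums(X)), rep(1, 5))  # one-hot block partition
  # numeric covariate only
  Xn <- build_confounder_matrix(
    ds, confounder_spec(use_cell_type = FALSE, numeric_covariates = "tot"))
  expect_equal(unname(Xn[, 1]), ds$covariates$tot)
  # reference level dropped
  Xd <- build_confounder_matrix(ds, confounder_spec(drop_reference_level = TRUE))
  expect_identical(colnames(Xd), "cell_type.T-cell")
  one <- spatial_dataset(matrix(1, 2, 2), cbind(1:2, 0), c("T", "T"))
  expect_warning(build_confounder_matrix(
    one, confounder_spec(drop_reference_level = TRUE)), "single level")
})

test_that("subsampling is deterministic, sorted, and well-mixed", {
  expect_identical(subsample_cells(100, 5000, seed = 1), 1:100)
  s1 <- subsample_cells(10000, 500, seed = 9)
  s2 <- subsample_cells(10000, 500, seed = 9)
  expect_identical(s1, s2)
  expect_identical(s1, sort(s1))
  expect_length(s1, 500)
  s3 <- subsample_cells(10000, 500, seed = 10)
  ov <- length(intersect(s1, s3))
  # hypergeometric expectation 500*500/10000 = 25
  expect_gt(ov, 5); expect_lt(ov, 60)
  expect_error(subsample_cells(10, 1, seed = 1), "max_cells")
})

test_that("conditional covariance equals OLS residual covariance", {
  set.seed(21)
  for (rep in 1:5) {
    Y <- matrix(rnorm(200 * 8), 200)
    X <- matrix(rnorm(200 * 3), 200)
    fit <- lm(Y ~ X)
    oracle <- cov(residuals(fit))
    expect_lt(max(abs(conditional_covariance(Y, X) - oracle)), 1e-8)
    expect_lt(max(abs(conditional_covariance(Y, X, method = "schur") - oracle)),
              1e-8)
  }
})

test_that("degenerate conditioning cases behave as identities", {
  set.seed(22)
  Y <- matrix(rnorm(50 * 4), 50)
  expect_identical(conditional_covariance(Y, matrix(0, 50, 0)), cov(Y))
  expect_identical(conditional_covariance(Y, NULL), cov(Y))
  # a gene fully explained by a confounder keeps ~zero conditional variance
  X <- cbind(Y[, 2], rnorm(50))
  cc <- conditional_covariance(Y, X)
  expect_lt(cc[2, 2], 1e-10)
  expect_error(conditional_covariance(Y[1:2, ], X[1:2, ]), "3 rows")
})

test_that("adding a linearly dependent confounder changes nothing", {
  set.seed(23)
  Y <- matrix(rnorm(150 * 6), 150)
  X <- matrix(rnorm(150 * 3), 150)
  X2 <- cbind(X, X[, 1] - 2 * X[, 3])
  for (m in c("residual", "schur"))
    expect_lt(max(abs(conditional_covariance(Y, X, method = m) -
                      conditional_covariance(Y, X2, method = m))), 1e-6)
})

test_that("empty conditioning reduces to Pearson correlation of Y^(N)", {
  inp <- small_pipeline_inputs()
  res <- conditional_correlation(
    inp$ds, inp$graph, confounder_spec(use_cell_type = FALSE),
    max_cells = 600, seed = 2)
  A <- neighbor_adjacency(inp$graph)
  sub <- subsample_cells(inp$graph$n_cells, 600, seed = 2)
  envY <- as.matrix(A[sub, ] %*% inp$ds$counts)
  expect_lt(max(abs(res$cond_cor - cor(envY))), 1e-12)
  # raw matrix equals the empty-spec conditional matrix
  raw <- raw_correlation(inp$ds, inp$graph, max_cells = 600, seed = 2)
  attr(raw, "zero_variance") <- NULL
  expect_equal(unname(raw), unname(res$cond_cor), tolerance = 1e-12)
})

test_that("gene-subset runs reproduce the full-run submatrix", {
  inp <- small_pipeline_inputs()
  full <- conditional_correlation(inp$ds, inp$graph, inp$spec,
                                  max_cells = 700, seed = 5)
  subset_genes <- c("A_mk01", "A_mk03", "mod1_g1", "mod1_g4", "bg01")
  part <- conditional_correlation(inp$ds, inp$graph, inp$spec,
                                  max_cells = 700, seed = 5,
                                  genes = subset_genes)
  expect_identical(part$genes, subset_genes)
  expect_lt(max(abs(part$cond_cor - full$cond_cor[subset_genes, subset_genes])),
            1e-10)
  expect_error(conditional_correlation(inp$ds, inp$graph, inp$spec,
                                       genes = c("no_such_gene")),
               "disjoint")
})

test_that("results are symmetric, bounded, and flag constant genes", {
  inp <- small_pipeline_inputs()
  ds <- inp$ds
  # append an all-constant gene
  counts <- cbind(as.matrix(ds$counts), dead_gene = 0)
  ds2 <- spatial_dataset(counts, ds$positions, ds$cell_type,
                         covariates = ds$covariates, cell_ids = ds$cell_ids,
                         normalized = FALSE)
  res <- conditional_correlation(ds2, inp$graph, inp$spec,
                                 max_cells = 500, seed = 8)
  expect_lt(max(abs(res$cond_cor - t(res$cond_cor))), 1e-10)
  expect_lte(max(abs(res$cond_cor)), 1)
  expect_true("dead_gene" %in% res$zero_variance_genes)
  expect_equal(unname(res$cond_cor["dead_gene", ]),
               rep(0, ncol(res$cond_cor)))
  pos_var <- setdiff(res$genes, res$zero_variance_genes)
  expect_equal(unname(diag(res$cond_cor[pos_var, pos_var])),
               rep(1, length(pos_var)))
})

test_that("Schur and residual paths agree on random confounded instances", {
  set.seed(31)
  worst <- 0
  for (rep in 1:20) {
    Y <- matrix(rnorm(200 * 10), 200)
    base <- matrix(rnorm(200 * 3), 200)
    X <- cbind(base, base[, 1] + base[, 2])  # collinear block
    d <- max(abs(conditional_covariance(Y, X) -
                 conditional_covariance(Y, X, method = "schur")))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-8)
})
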