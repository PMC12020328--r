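test_that("MTX round-trip aligns cells by id in metadata order", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  export_simulation(sim, dir)
  ds <- load_dataset(file.path(dir, "counts.mtx"),
                     file.path(dir, "metadata.csv"))
  expect_identical(ds$cell_ids, sim$dataset$cell_ids)
  expect_identical(ds$gene_ids, sim$dataset$gene_ids)
  expect_equal(as.matrix(ds$counts), as.matrix(sim$dataset$counts),
               ignore_attr = TRUE)
  expect_equal(ds$positions, sim$dataset$positions, ignore_attr = TRUE)
  expect_identical(as.character(ds$cell_type),
                   as.character(sim$dataset$cell_type))
  expect_true("negprobes" %in% names(ds$covariates))
})

test_that("cells present in only one file are dropped and reported", {
  dir <- withr::local_tempdir()
  counts <- matrix(1:6, nrow = 3,
                   dimnames = list(c("c1", "c2", "c3"), c("g1", "g2")))
  write.csv(data.frame(cell_id = rownames(counts), counts),
            file.path(dir, "counts.csv"), row.names = FALSE, quote = FALSE)
  md <- data.frame(cell_id = c("c2", "c1", "c3", "c4"),
                   x = c(1, 2, 3, 4), y = 0,
                   cell_type = "T")
  write.csv(md, file.path(dir, "md.csv"), row.names = FALSE, quote = FALSE)
  expect_message(
    ds <- load_dataset(file.path(dir, "counts.csv"), file.path(dir, "md.csv")),
    "dropped")
  # metadata order wins; c4 has no counts
  expect_identical(ds$cell_ids, c("c2", "c1", "c3"))
  expect_match(attr(ds, "dropped_cells"), "c4", all = FALSE)
  expect_equal(unname(as.matrix(ds$counts)["c2", ]), c(2, 5))
})

test_that("negative counts and disjoint ids are fatal", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(cell_id = "c1", g1 = -1),
            file.path(dir, "neg.csv"), row.names = FALSE, quote = FALSE)
  md <- data.frame(cell_id = "c1", x = 0, y = 0, cell_type = "T")
  write.csv(md, file.path(dir, "md.csv"), row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(file.path(dir, "neg.csv"),
                            file.path(dir, "md.csv")),
               "negative")
  write.csv(data.frame(cell_id = "zz", g1 = 1),
            file.path(dir, "other.csv"), row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(file.path(dir, "other.csv"),
                            file.path(dir, "md.csv")),
               "no overlap")
})

test_that("count filter keeps cells at the boundary and is idempotent", {
  counts <- matrix(c(5, 0, 0,
                     10, 5, 5,
                     40, 30, 30), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("c", 1:3), paste0("g", 1:3)))
  ds <- spatial_dataset(counts, cbind(1:3, 0), rep("T", 3))
  f <- filter_min_counts(ds, 20)
  expect_identical(f$cell_ids, c("c2", "c3"))
  expect_identical(filter_min_counts(f, 20)$cell_ids, f$cell_ids)
  expect_identical(filter_min_counts(ds, 0)$cell_ids, ds$cell_ids)
})

test_that("filter matches a row-sum oracle on Poisson totals", {
  set.seed(77)
  counts <- matrix(rpois(100 * 5, 6), nrow = 100)
  ds <- spatial_dataset(counts, cbind(runif(100), runif(100)),
                        sample(c("a", "b"), 100, TRUE))
  f <- filter_min_counts(ds, 25)
  expect_identical(f$cell_ids, ds$cell_ids[rowSums(counts) >= 25])
  expect_error(filter_min_counts(normalize_total_counts(f), 25),
               "raw counts")
})

test_that("normalization divides rows by totals exactly once", {
  ds <- tiny_dataset()
  nd <- normalize_total_counts(ds)
  expect_equal(unname(as.matrix(nd$counts)["c1", ]), c(4, 0, 1, 0) / 5)
  expect_equal(unname(Matrix::rowSums(nd$counts)), rep(1, 6),
               tolerance = 1e-12)
  expect_true(nd$normalized)
  expect_equal(nd$covariates$total_counts, unname(rowSums(as.matrix(ds$counts))))
  expect_error(normalize_total_counts(nd), "already normalized")
  zero <- spatial_dataset(matrix(0, 2, 2), cbind(1:2, 0), c("T", "T"))
  expect_error(normalize_total_counts(zero), "zero total")
})

test_that("result writers round-trip matrices and honor overwrite", {
  dir <- withr::local_tempdir()
  inp <- small_pipeline_inputs()
  cc <- conditional_correlation(inp$ds, inp$graph, inp$spec,
                                max_cells = 800, seed = 4)
  write_results(cc, dir)
  back <- read_result_matrix(file.path(dir, "cond_cor.csv"))
  expect_lt(max(abs(back - cc$cond_cor)), 1e-9)
  expect_error(write_results(cc, dir), "exists")
  expect_silent(write_results(cc, dir, overwrite = TRUE))
  # long form covers every unordered pair once, gene_a < gene_b
  pairs <- read.delim(file.path(dir, "cor_pairs.tsv"))
  expect_equal(nrow(pairs), choose(length(cc$genes), 2))
  expect_true(all(pairs$gene_a < pairs$gene_b))
})

test_that("module writer emits disjoint labeled genes, or a header when empty", {
  dir <- withr::local_tempdir()
  # two disjoint correlated pairs
  m <- sym_from_upper(c("a", "b", "c", "d"),
                      c(0.9, 0, 0, 0, 0, 0.8))
  ms <- detect_modules(threshold_adjacency(m, 0.2), cond_cor = m,
                       min_size = 2, seed = 1)
  # fill weights as the pipeline would
  for (q in seq_along(ms$modules))
    ms$modules[[q]]$weights[] <- 1
  write_results(ms, dir)
  tab <- read.delim(file.path(dir, "modules.tsv"))
  expect_equal(length(unique(tab$module)), 2)
  expect_false(any(duplicated(tab$gene)))

  empty <- detect_modules(matrix(0, 3, 3), seed = 1)
  dir2 <- withr::local_tempdir()
  write_results(empty, dir2)
  tab2 <- read.delim(file.path(dir2, "modules.tsv"))
  expect_equal(nrow(tab2), 0)
  expect_identical(names(tab2), c("module", "gene", "weight"))
})
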