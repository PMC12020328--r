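#' Configure a synthetic spatial transcriptomics simulation
#'
#' The simulator emulates the structure the conditional-correlation method
#' assumes in real tissue: cell types laid out as spatial clusters (Gaussian
#' niches), cell-type-specific marker expression, optional planted latent
#' co-expression programs that vary smoothly in space, per-cell sequencing
#' depth, and uniform background noise. Counts for cell `i`, gene `j` are
#' drawn as
#' `Poisson(depth_i * mu[type_i, j] * (1 + sum_m amp_m * field_m(i) * I(j in
#' module m, type_i affected)) + background)`.
#'
#' @param n_cells Number of cells.
#' @param arena Width and height of the rectangular tissue, in length units
#'   (defaults emulate a ~2 mm square region).
#' @param n_cell_types Number of cell types (named `A`, `B`, ...), each with
#'   equal proportion and its own spatial niches.
#' @param niches_per_type Gaussian niche centers per cell type.
#' @param niche_sd Spatial spread of each niche (same units as `arena`).
#' @param mixing Fraction of cells placed uniformly at random rather than in
#'   a niche (spatial mixing of types).
#' @param n_marker_genes Marker genes per cell type.
#' @param marker_rate Mean count rate of a marker in its own type.
#' @param off_rate Mean rate of any gene in types where it is not expressed.
#' @param planted_modules List of planted programs; each element a list with
#'   `n_genes` (default 6), `affected_cell_types` (default the first type),
#'   `n_bumps` (default 60), `bump_radius` (default 0.12), `amplitude`
#'   (default 2), `base_rate` (default 1). The bump radius is wider than a
#'   50-cell neighborhood, so programs stay coherent within neighborhoods,
#'   while many bumps give each field enough spatial degrees of freedom that
#'   distinct programs stay distinguishable. Amplitudes were calibrated once so
#'   planted programs stand clearly above the spatial-autocorrelation noise
#'   floor while perturbing cell totals by only a few percent.
#' @param n_background_genes Housekeeping genes expressed at
#'   `background_gene_rate` in every type. They carry most of each cell's
#'   total counts, as in a real panel, so a planted program perturbs cell
#'   totals (and hence normalized proportions) only mildly.
#' @param background_gene_rate Mean rate of background genes.
#' @param background Additive uniform noise rate for every gene.
#' @param depth_meanlog,depth_sdlog Log-normal per-cell size-factor model.
#' @param negprobe_rate Mean negative-control-probe count per unit depth.
#' @param seed Master seed; all randomness derives from it through fixed
#'   per-component streams.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cells = 10000, arena = c(2, 2),
                              n_cell_types = 3, niches_per_type = 2,
                              niche_sd = 0.35, mixing = 0.15,
                              n_marker_genes = 10, marker_rate = 5,
                              off_rate = 0.05,
                              planted_modules = list(),
                              n_background_genes = 30,
                              background_gene_rate = 15,
                              background = 0.01,
                              depth_meanlog = 0, depth_sdlog = 0.3,
                              negprobe_rate = 0.5, seed = 1L) {
  types <- LETTERS[seq_len(n_cell_types)]
  pm <- lapply(seq_along(planted_modules), function(q) {
    m <- utils::modifyList(
      list(n_genes = 6, affected_cell_types = types[1], n_bumps = 60,
           bump_radius = 0.12, amplitude = 2, base_rate = 1),
      planted_modules[[q]])
    if (m$amplitude < 0) stop("amplitude must be >= 0")
    if (is.null(m$name)) m$name <- paste0("mod", q)
    m
  })
  structure(
    list(n_cells = as.integer(n_cells), arena = arena, types = types,
         niches_per_type = niches_per_type, niche_sd = niche_sd,
         mixing = mixing, n_marker_genes = n_marker_genes,
         marker_rate = marker_rate, off_rate = off_rate,
         planted_modules = pm,
         n_background_genes = n_background_genes,
         background_gene_rate = background_gene_rate,
         background = background, depth_meanlog = depth_meanlog,
         depth_sdlog = depth_sdlog, negprobe_rate = negprobe_rate,
         seed = as.integer(seed)),
    class = "simulation_config")
}

sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset * 1000003) %% 2147483647)
}

#' Simulate a spatial dataset with known ground truth
#'
#' @param cfg A [simulation_config()].
#' @return List with `dataset` (a raw-count [spatial_dataset()] with a
#'   `negprobes` covariate) and `truth` (a `synthetic_truth`:
#'   `module_membership` gene -> module name, `latent_field_values`
#'   cells x modules, `type_assignments`, `depth`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_cells
  types <- cfg$types
  k_types <- length(types)

  # niche centers per type
  centers <- with_seed(sub_seed(cfg$seed, 1), lapply(seq_len(k_types), function(t)
    cbind(runif(cfg$niches_per_type, 0, cfg$arena[1]),
          runif(cfg$niches_per_type, 0, cfg$arena[2]))))

  # cell types and positions
  placement <- with_seed(sub_seed(cfg$seed, 2), {
    ct <- sample.int(k_types, n, replace = TRUE)
    uni <- runif(n) < cfg$mixing
    which_niche <- sample.int(cfg$niches_per_type, n, replace = TRUE)
    px <- numeric(n); py <- numeric(n)
    for (i in seq_len(n)) {
      if (uni[i]) {
        px[i] <- runif(1, 0, cfg$arena[1])
        py[i] <- runif(1, 0, cfg$arena[2])
      } else {
        cen <- centers[[ct[i]]][which_niche[i], ]
        px[i] <- rnorm(1, cen[1], cfg$niche_sd)
        py[i] <- rnorm(1, cen[2], cfg$niche_sd)
      }
    }
    # reflect into the arena so density stays bounded
    px <- abs(px); px <- cfg$arena[1] - abs(cfg$arena[1] - px)
    py <- abs(py); py <- cfg$arena[2] - abs(cfg$arena[2] - py)
    list(ct = ct, pos = cbind(px, py))
  })
  ct <- placement$ct
  pos <- placement$pos

  # gene panel: per-type markers, planted module genes, background genes
  marker_names <- unlist(lapply(types, function(t)
    sprintf("%s_mk%02d", t, seq_len(cfg$n_marker_genes))))
  module_names <- unlist(lapply(cfg$planted_modules, function(m)
    sprintf("%s_g%d", m$name, seq_len(m$n_genes))))
  bg_names <- if (cfg$n_background_genes)
    sprintf("bg%02d", seq_len(cfg$n_background_genes)) else character(0)
  genes <- c(marker_names, module_names, bg_names)

  mu <- matrix(cfg$off_rate, k_types, length(genes),
               dimnames = list(types, genes))
  for (t in seq_len(k_types))
    mu[t, sprintf("%s_mk%02d", types[t], seq_len(cfg$n_marker_genes))] <-
      cfg$marker_rate
  for (m in cfg$planted_modules)
    mu[m$affected_cell_types, sprintf("%s_g%d", m$name, seq_len(m$n_genes))] <-
      m$base_rate
  if (length(bg_names)) mu[, bg_names] <- cfg$background_gene_rate

  # Latent fields: sums of isotropic Gaussian bumps. Smooth random fields
  # have few effective degrees of freedom, so two of them can correlate
  # substantially by chance, which would make the planted "distinct
  # programs" ground truth ill-posed. Successive fields are therefore
  # orthogonalized against earlier ones (Gram-Schmidt over cells) before
  # min-max rescaling to [0, 1].
  n_mod <- length(cfg$planted_modules)
  fields <- matrix(0, n, max(n_mod, 1))
  if (n_mod) {
    fields <- with_seed(sub_seed(cfg$seed, 3), {
      f <- matrix(0, n, n_mod)
      for (q in seq_len(n_mod)) {
        m <- cfg$planted_modules[[q]]
        bx <- runif(m$n_bumps, 0, cfg$arena[1])
        by <- runif(m$n_bumps, 0, cfg$arena[2])
        v <- numeric(n)
        for (b in seq_len(m$n_bumps)) {
          d2 <- (pos[, 1] - bx[b])^2 + (pos[, 2] - by[b])^2
          v <- v + exp(-d2 / (2 * m$bump_radius^2))
        }
        if (q > 1) {
          prev <- f[, seq_len(q - 1), drop = FALSE]
          v <- residuals(lm.fit(cbind(1, prev), v))
        }
        f[, q] <- (v - min(v)) / (max(v) - min(v))
      }
      f
    })
  }

  depth <- with_seed(sub_seed(cfg$seed, 4),
                     rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog))

  lam <- depth * mu[ct, , drop = FALSE]
  if (n_mod) {
    for (q in seq_len(n_mod)) {
      m <- cfg$planted_modules[[q]]
      gcols <- sprintf("%s_g%d", m$name, seq_len(m$n_genes))
      boost <- 1 + m$amplitude * fields[, q] *
        (types[ct] %in% m$affected_cell_types)
      lam[, gcols] <- lam[, gcols] * boost
    }
  }
  lam <- lam + cfg$background

  counts <- with_seed(sub_seed(cfg$seed, 5), {
    m <- matrix(rpois(length(lam), as.numeric(lam)), n, ncol(lam))
    colnames(m) <- genes
    m
  })
  negprobes <- with_seed(sub_seed(cfg$seed, 6),
                         rpois(n, depth * cfg$negprobe_rate))

  ds <- spatial_dataset(
    counts = counts, positions = pos, cell_type = types[ct],
    covariates = data.frame(negprobes = negprobes),
    cell_ids = sprintf("c%06d", seq_len(n)))

  membership <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (m in cfg$planted_modules)
    membership[sprintf("%s_g%d", m$name, seq_len(m$n_genes))] <- m$name
  truth <- structure(
    list(module_membership = membership,
         latent_field_values = if (n_mod) fields else NULL,
         type_assignments = types[ct], depth = depth),
    class = "synthetic_truth")
  list(dataset = ds, truth = truth)
}

#' Simulate a multi-sample cohort
#'
#' Generates one dataset per sample with a shared gene panel and
#' per-sample seeds (`seed + 1000 * s`), concatenated into a single
#' [spatial_dataset()] with `sample_id`. Planted programs can be switched off
#' in chosen samples (`active[[module name]]` = sample indices where the
#' module is active, amplitude 0 elsewhere), producing inter-sample-variable
#' gene pairs.
#'
#' @param cfg A [simulation_config()] describing one sample.
#' @param n_samples Number of samples.
#' @param active Optional named list: module name -> integer vector of
#'   samples where the module is active (default: active everywhere).
#' @return List with `dataset` (combined, with `sample_id` `s1, s2, ...`)
#'   and `truths` (per-sample list).
#' @export
simulate_cohort <- function(cfg, n_samples, active = NULL) {
  sims <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(cfg$seed + 1000 * s)
    if (!is.null(active)) {
      for (q in seq_along(cfg_s$planted_modules)) {
        nm <- cfg_s$planted_modules[[q]]$name
        if (nm %in% names(active) && !(s %in% active[[nm]]))
          cfg_s$planted_modules[[q]]$amplitude <- 0
      }
    }
    sims[[s]] <- simulate_dataset(cfg_s)
  }
  ids <- paste0("s", seq_len(n_samples))
  counts <- do.call(rbind, lapply(sims, function(x) x$dataset$counts))
  pos <- do.call(rbind, lapply(sims, function(x) x$dataset$positions))
  ctype <- unlist(lapply(sims, function(x) as.character(x$dataset$cell_type)))
  covs <- do.call(rbind, lapply(sims, function(x) x$dataset$covariates))
  sample_id <- rep(ids, vapply(sims, function(x) nrow(x$dataset$counts), 1L))
  cell_ids <- paste0(sample_id, "_",
                     unlist(lapply(sims, function(x) x$dataset$cell_ids)))
  ds <- spatial_dataset(counts = counts, positions = pos, cell_type = ctype,
                        covariates = covs, sample_id = sample_id,
                        cell_ids = cell_ids)
  list(dataset = ds, truths = stats::setNames(lapply(sims, `[[`, "truth"), ids))
}

#' Export a simulated dataset in the on-disk input formats
#'
#' Writes the MatrixMarket counts (genes x cells, with `features.tsv` /
#' `barcodes.tsv` sidecars), the metadata CSV, and a `truth.json`, i.e.
#' exactly what [load_dataset()] reads.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  m <- Matrix::Matrix(t(as.matrix(ds$counts)), sparse = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(m, mtx)
  writeLines(ds$gene_ids, file.path(dir, "counts_features.tsv"))
  writeLines(ds$cell_ids, file.path(dir, "counts_barcodes.tsv"))
  md <- data.frame(cell_id = ds$cell_ids, x = ds$positions[, 1],
                   y = ds$positions[, 2],
                   cell_type = as.character(ds$cell_type),
                   stringsAsFactors = FALSE)
  if (!is.null(ds$covariates)) md <- cbind(md, ds$covariates)
  if (!is.null(ds$sample_id)) md$sample <- as.character(ds$sample_id)
  write.table(md, file.path(dir, "metadata.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(module_membership = as.list(
      sim$truth$module_membership[!is.na(sim$truth$module_membership)])),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(c(mtx, file.path(dir, "metadata.csv"),
              file.path(dir, "truth.json")))
}

#' Compare recovered modules with the planted truth
#'
#' Pairwise precision/recall/F1 are computed over unordered within-module
#' gene pairs: precision is the fraction of recovered pairs that are truth
#' pairs, recall the fraction of truth pairs recovered. Genes in no planted
#' module contribute false-positive pairs only. The adjusted Rand index is
#' computed over the union of genes placed in any truth or recovered module,
#' with a gene absent from one partition treated as its own singleton there.
#'
#' @param modules A `module_set`.
#' @param truth A `synthetic_truth`.
#' @return List: `precision`, `recall`, `f1`, `ari`,
#'   `precision_defined` (FALSE when no pairs were recovered; precision and
#'   F1 are then reported as 0).
#' @export
evaluate_recovery <- function(modules, truth) {
  stopifnot(inherits(modules, "module_set"), inherits(truth, "synthetic_truth"))
  pair_set <- function(groups) {
    out <- character(0)
    for (g in groups) {
      g <- sort(g)
      if (length(g) >= 2) {
        cmb <- utils::combn(g, 2)
        out <- c(out, paste(cmb[1, ], cmb[2, ], sep = "|"))
      }
    }
    unique(out)
  }
  truth_mem <- truth$module_membership[!is.na(truth$module_membership)]
  truth_groups <- split(names(truth_mem), truth_mem)
  rec_groups <- lapply(modules$modules, `[[`, "genes")
  tp_pairs <- pair_set(truth_groups)
  rc_pairs <- pair_set(rec_groups)
  inter <- length(intersect(tp_pairs, rc_pairs))
  precision_defined <- length(rc_pairs) > 0
  precision <- if (precision_defined) inter / length(rc_pairs) else 0
  recall <- if (length(tp_pairs)) inter / length(tp_pairs) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0

  genes <- sort(unique(c(names(truth_mem), unlist(rec_groups))))
  lab_of <- function(groups, prefix) {
    lab <- stats::setNames(paste0(prefix, "_none_", seq_along(genes)), genes)
    for (q in seq_along(groups))
      lab[intersect(groups[[q]], genes)] <- paste0(prefix, "_", q)
    lab
  }
  ari <- if (length(genes) >= 2)
    mclust::adjustedRandIndex(lab_of(truth_groups, "t")[genes],
                              lab_of(rec_groups, "r")[genes]) else NA_real_
  list(precision = precision, recall = recall, f1 = f1, ari = ari,
       precision_defined = precision_defined)
}
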