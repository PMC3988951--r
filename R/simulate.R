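#' Specification of one planted co-expression module
#'
#' Each module is driven by a latent factor per region; member genes load on
#' that factor with per-gene loadings drawn uniformly from `loading_range`,
#' giving a hub gradient (high-loading genes are hubs). Loadings are shared
#' across all regions the module is present in, so the module is preserved
#' across regions even though factor values (individuals) differ.
#'
#' @param size Number of member genes.
#' @param loading_range Length-2 numeric in `[0, 1]`, low/high per-gene
#'   loading (correlation of a gene with the latent factor).
#' @param present_in_regions Integer vector of region indices the module
#'   exists in.
#' @param seed_gene_loading Optional loading forced on the designated seed
#'   gene, which is made a member of this module (use the maximum of
#'   `loading_range` to plant a hub).
#' @return A `module_spec` list.
#' @export
module_spec <- function(size, loading_range = c(0.6, 0.9),
                        present_in_regions, seed_gene_loading = NULL) {
  stopifnot(size >= 1, length(loading_range) == 2)
  if (!(loading_range[1] >= 0 && loading_range[1] <= loading_range[2] &&
        loading_range[2] <= 1))
    stop("loading_range must satisfy 0 <= low <= high <= 1")
  if (length(present_in_regions) < 1) stop("present_in_regions must be non-empty")
  if (!is.null(seed_gene_loading))
    stopifnot(seed_gene_loading >= 0, seed_gene_loading <= 1)
  structure(list(size = as.integer(size),
                 loading_range = as.numeric(loading_range),
                 present_in_regions = as.integer(present_in_regions),
                 seed_gene_loading = seed_gene_loading),
            class = "module_spec")
}

#' Configuration for the multi-region expression simulator
#'
#' Defaults emulate the design of a multi-region post-mortem brain
#' expression study: ~10 regional datasets of 65-88 samples drawn from a
#' shared pool of individuals, thousands of genes, a handful of latent-factor
#' modules (one present in every region and containing a designated seed
#' gene), additive batch offsets, and a linear age trend on selected genes.
#'
#' @param n_regions Number of regional datasets.
#' @param n_samples_per_region Samples per region: either a single count or a
#'   vector of length `n_regions`.
#' @param n_genes Total number of genes (module members plus background).
#' @param modules List of [module_spec()] objects; their gene sets are
#'   disjoint and their total size must not exceed `n_genes`.
#' @param batch_sd SD (log2 units) of the additive per-batch offset; 0
#'   disables batch effects.
#' @param n_batches Number of hybridisation batches per region.
#' @param age_range Length-2 numeric, years; individual ages are uniform on
#'   this range.
#' @param age_effect_genes Character vector of gene ids given a linear age
#'   trend (ids among `g0001`-style generated ids), or integer count of
#'   background genes to pick.
#' @param age_slope Log2 units per year for age-trend genes.
#' @param noise_sd Positive SD multiplier for the unit-variance
#'   factor-plus-noise signal.
#' @param n_individuals Size of the shared individual pool regions sample
#'   from (must be >= max samples per region).
#' @param seed Integer RNG seed; a single stream drives the whole simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 10,
                       n_samples_per_region = 80,
                       n_genes = 2000,
                       modules = list(),
                       batch_sd = 0,
                       n_batches = 2,
                       age_range = c(16, 83),
                       age_effect_genes = character(),
                       age_slope = 0.01,
                       noise_sd = 1,
                       n_individuals = NULL,
                       seed = 1L) {
  stopifnot(n_regions >= 1, n_genes >= 1, noise_sd > 0, batch_sd >= 0,
            length(age_range) == 2, age_range[1] <= age_range[2])
  if (length(n_samples_per_region) == 1)
    n_samples_per_region <- rep(n_samples_per_region, n_regions)
  stopifnot(length(n_samples_per_region) == n_regions,
            all(n_samples_per_region >= 3))
  for (m in modules)
    if (!inherits(m, "module_spec")) stop("modules must be module_spec objects")
  total <- sum(vapply(modules, function(m) m$size, integer(1)))
  if (total > n_genes)
    stop("configuration error: module sizes (", total,
         ") exceed n_genes (", n_genes, ")")
  for (m in modules)
    if (any(m$present_in_regions < 1 | m$present_in_regions > n_regions))
      stop("module present_in_regions outside 1..n_regions")
  if (is.null(n_individuals)) n_individuals <- max(n_samples_per_region)
  stopifnot(n_individuals >= max(n_samples_per_region))
  structure(list(n_regions = as.integer(n_regions),
                 n_samples_per_region = as.integer(n_samples_per_region),
                 n_genes = as.integer(n_genes),
                 modules = modules,
                 batch_sd = batch_sd,
                 n_batches = as.integer(n_batches),
                 age_range = age_range,
                 age_effect_genes = age_effect_genes,
                 age_slope = age_slope,
                 noise_sd = noise_sd,
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate multi-region expression data with planted modules
#'
#' For every region, genes belonging to a module present there are generated
#' as `loading * factor + sqrt(1 - loading^2) * noise` (unit variance, so the
#' expected correlation of two members is the product of their loadings),
#' scaled by `noise_sd` and shifted by a per-gene baseline; background genes
#' are independent noise. Batch offsets and age trends are then added.
#' Identical seeds give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{matrices}{List of [expression_matrix()] objects, one per region
#'       (regions named `R01`, `R02`, ...).}
#'     \item{truth}{Ground truth: `module_labels` (per-region list of
#'       gene -> module label, `"unassigned"` for background), `loadings`
#'       (named per-gene loading vector), `seed_gene` (id or `NA`),
#'       `age_effect_genes`, and the `config`.}
#'   }
#' @export
generate_multiregion_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  regions <- sprintf("R%02d", seq_len(config$n_regions))

  # assign disjoint gene blocks to modules, in declaration order
  mod_genes <- list()
  cursor <- 1L
  seed_gene <- NA_character_
  loadings <- stats::setNames(rep(NA_real_, config$n_genes), genes)
  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    idx <- seq.int(cursor, cursor + m$size - 1L)
    cursor <- cursor + m$size
    g <- genes[idx]
    lam <- stats::runif(m$size, m$loading_range[1], m$loading_range[2])
    if (!is.null(m$seed_gene_loading)) {
      if (!is.na(seed_gene)) stop("only one module may designate a seed gene")
      seed_gene <- g[1]
      lam[1] <- m$seed_gene_loading
    }
    loadings[g] <- lam
    mod_genes[[paste0("M", i)]] <- g
  }

  # age-trend genes: count -> sample from background
  background <- setdiff(genes, unlist(mod_genes))
  age_genes <- config$age_effect_genes
  if (is.numeric(age_genes)) {
    stopifnot(age_genes <= length(background))
    age_genes <- sample(background, age_genes)
  } else if (length(age_genes) && !all(age_genes %in% genes)) {
    stop("age_effect_genes not among generated gene ids")
  }

  baseline <- stats::runif(config$n_genes, 6, 12)   # log2 array-like baselines
  names(baseline) <- genes

  # shared individual pool: ids, ages, sex
  ind_ids <- sprintf("I%03d", seq_len(config$n_individuals))
  ages <- stats::runif(config$n_individuals, config$age_range[1], config$age_range[2])
  sexes <- sample(c("M", "F"), config$n_individuals, replace = TRUE)

  matrices <- vector("list", config$n_regions)
  names(matrices) <- regions
  module_labels <- vector("list", config$n_regions)
  names(module_labels) <- regions

  for (r in seq_len(config$n_regions)) {
    n <- config$n_samples_per_region[r]
    picked <- sort(sample.int(config$n_individuals, n))
    samp_ids <- paste0(regions[r], "_", ind_ids[picked])

    vals <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                   dimnames = list(genes, samp_ids))
    lab <- stats::setNames(rep(UNASSIGNED, config$n_genes), genes)
    for (mn in names(mod_genes)) {
      m <- config$modules[[as.integer(sub("M", "", mn))]]
      if (!(r %in% m$present_in_regions)) next
      g <- mod_genes[[mn]]
      f <- stats::rnorm(n)                       # latent factor, new per region
      lam <- loadings[g]
      vals[g, ] <- lam %o% f + sqrt(1 - lam^2) * vals[g, , drop = FALSE]
      lab[g] <- mn
    }
    vals <- config$noise_sd * vals + baseline

    batch <- sample(seq_len(config$n_batches), n, replace = TRUE)
    if (config$batch_sd > 0) {
      offs <- stats::rnorm(config$n_batches, 0, config$batch_sd)
      vals <- vals + matrix(offs[batch], config$n_genes, n, byrow = TRUE)
    }
    if (length(age_genes)) {
      a <- ages[picked]
      vals[age_genes, ] <- vals[age_genes, , drop = FALSE] +
        rep(config$age_slope * (a - mean(a)), each = length(age_genes))
    }

    md <- data.frame(sample_id = samp_ids,
                     region = regions[r],
                     individual = ind_ids[picked],
                     age = ages[picked],
                     sex = sexes[picked],
                     batch = paste0("B", batch),
                     stringsAsFactors = FALSE)
    matrices[[r]] <- expression_matrix(vals, region = regions[r], metadata = md)
    module_labels[[r]] <- lab
  }

  truth <- list(module_labels = module_labels,
                loadings = loadings,
                module_genes = mod_genes,
                seed_gene = seed_gene,
                age_effect_genes = age_genes,
                config = config)
  list(matrices = matrices, truth = truth)
}

#' Build a gene set with a controlled overlap against a planted module
#'
#' Emulates an externally curated disease or marker gene list: exactly
#' `target_overlap` genes are drawn from the designated planted module and
#' the remainder from background genes, so the downstream hypergeometric
#' enrichment has a known expected strength.
#'
#' @param truth Ground truth from [generate_multiregion_dataset()].
#' @param module Module name (e.g. `"M1"`).
#' @param target_overlap Number of set genes inside the module.
#' @param set_size Total set size.
#' @param seed Integer RNG seed.
#' @param name Set name.
#' @return A `gene_set` list (`name`, `genes`, `source`).
#' @export
generate_gene_sets <- function(truth, module = "M1", target_overlap, set_size,
                               seed = 1L, name = "synthetic_set") {
  mod <- truth$module_genes[[module]]
  if (is.null(mod)) stop("unknown module: ", module)
  background <- setdiff(names(truth$loadings), unlist(truth$module_genes))
  if (target_overlap > min(set_size, length(mod)))
    stop("infeasible overlap: target_overlap exceeds set or module size")
  if (set_size - target_overlap > length(background))
    stop("infeasible overlap: not enough background genes")
  set.seed(seed)
  inside <- if (target_overlap > 0) sample(mod, target_overlap) else character()
  outside <- if (set_size > target_overlap)
    sample(background, set_size - target_overlap) else character()
  gene_set(name, c(inside, outside), source = "synthetic")
}

#' Write a simulated dataset to disk
#'
#' Emits one expression TSV per region, a combined sample-metadata TSV, and
#' the ground truth as JSON.
#'
#' @param sim Result of [generate_multiregion_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (r in names(sim$matrices)) {
    f <- file.path(dir, paste0("expression_", r, ".tsv"))
    write_expression_tsv(sim$matrices[[r]], f)
    files <- c(files, f)
  }
  md <- do.call(rbind, lapply(sim$matrices, function(m) m$metadata))
  mf <- file.path(dir, "sample_metadata.tsv")
  utils::write.table(md, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  tf <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$config$modules <- lapply(truth$config$modules, unclass)
  jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, mf, tf))
}
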