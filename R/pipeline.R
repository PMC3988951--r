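#' Pipeline configuration
#'
#' Bundles every input path and stage parameter of the end-to-end analysis.
#' Defaults are the conventional parameters of the signed co-expression
#' workflow: soft power 12, minimum module size 30, eigengene merge height
#' 0.1, TOM edge threshold 0.10, hub quantile 0.90, core quantile 0.80.
#'
#' @param expression_paths Named character vector of expression TSV paths,
#'   names = region labels.
#' @param metadata_path Sample metadata TSV (`sample_id`, `region`,
#'   `individual`, `age`, `sex`, `batch`).
#' @param detection_paths Optional named vector of detection-flag TSVs
#'   aligned with `expression_paths`.
#' @param gmt_path Optional GMT file of annotation sets for enrichment.
#' @param seed_gene Gene id whose module is the analysis target.
#' @param out_dir Output directory.
#' @param beta Soft power used when `pick_power = FALSE`.
#' @param pick_power Select the power by scale-free fit per region.
#' @param r2_cut Scale-free signed r2 threshold for power selection.
#' @param min_size,merge_height,cut_height Module detection parameters.
#' @param tom_min TOM edge threshold for the seed neighbourhood.
#' @param hub_q,hub_min_regions Hub rule: MM quantile and region count.
#' @param core_q Core-set quantile.
#' @param n_perm Preservation permutations (0 disables preservation).
#' @param residualize_on Metadata columns regressed out per region (columns
#'   with fewer than 2 levels are skipped).
#' @param iac_sd Outlier threshold in SDs of the mean inter-array
#'   correlation.
#' @param criteria A [filter_criteria()].
#' @param seed Integer seed driving all randomness in the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression_paths, metadata_path,
                            detection_paths = NULL, gmt_path = NULL,
                            seed_gene, out_dir,
                            beta = 12, pick_power = FALSE, r2_cut = 0.8,
                            min_size = 30, merge_height = 0.1,
                            cut_height = NULL, tom_min = 0.10,
                            hub_q = 0.90, hub_min_regions = 5,
                            core_q = 0.80, n_perm = 100,
                            residualize_on = c("batch"),
                            iac_sd = 3, criteria = filter_criteria(),
                            seed = 1L) {
  if (is.null(names(expression_paths)) || any(!nzchar(names(expression_paths))))
    stop("expression_paths must be named by region")
  structure(list(expression_paths = expression_paths,
                 metadata_path = metadata_path,
                 detection_paths = detection_paths,
                 gmt_path = gmt_path,
                 seed_gene = seed_gene, out_dir = out_dir,
                 beta = beta, pick_power = pick_power, r2_cut = r2_cut,
                 min_size = min_size, merge_height = merge_height,
                 cut_height = cut_height, tom_min = tom_min,
                 hub_q = hub_q, hub_min_regions = hub_min_regions,
                 core_q = core_q, n_perm = n_perm,
                 residualize_on = residualize_on,
                 iac_sd = iac_sd, criteria = criteria,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full co-expression analysis pipeline
#'
#' Stages: read inputs, transcript filtering, covariate residualization,
#' outlier-sample removal, per-region network construction (fixed or
#' scale-free-selected power), module detection and eigengene merging,
#' identification of the target module (the one containing the seed gene),
#' pairwise target-module overlap tests, permutation Zsummary preservation
#' of the first region's target module in every other region, hub and core
#' gene extraction, optional gene-set enrichment of the core set, TOM
#' neighbourhood of the seed gene, and regional expression contrasts for the
#' seed gene. All outputs are written under `config$out_dir` together with a
#' JSON run manifest recording every parameter; identical configurations
#' reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (`networks`,
#'   `modules`, `target_modules`, `hubs`, `core`, `preservation`,
#'   `overlap`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(config$expression_paths, config$metadata_path,
             config$detection_paths, config$gmt_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  regions <- names(config$expression_paths)
  md_all <- stage("read", read_metadata_tsv(config$metadata_path))
  matrices <- stage("read", lapply(regions, function(r)
    read_expression_tsv(config$expression_paths[[r]], region = r,
                        metadata = md_all)))
  names(matrices) <- regions

  detected <- NULL
  if (!is.null(config$detection_paths))
    detected <- stage("read", lapply(config$detection_paths, read_detection_tsv))

  filt <- stage("filter", filter_transcripts(matrices, detected,
                                             config$criteria))
  matrices <- filt$matrices
  utils::write.table(filt$report, file.path(config$out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  matrices <- stage("residualize", lapply(matrices, function(m) {
    covs <- intersect(config$residualize_on, names(m$metadata))
    covs <- covs[vapply(covs, function(cv)
      length(unique(m$metadata[[cv]])) >= 2, logical(1))]
    if (length(covs)) residualize(m, covs) else m
  }))

  matrices <- stage("outliers", lapply(matrices, function(m) {
    bad <- detect_outlier_samples(m, sd_threshold = config$iac_sd)
    if (length(bad)) subset_expr(m, samples = setdiff(sample_ids(m), bad))
    else m
  }))

  networks <- list(); mods <- list(); betas <- integer()
  for (r in regions) {
    b <- config$beta
    if (config$pick_power) {
      pick <- stage("power", pick_soft_threshold(matrices[[r]],
                                                 r2_cut = config$r2_cut))
      b <- pick$beta
      utils::write.table(pick$fits,
                         file.path(config$out_dir, paste0("power_fit_", r, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    betas[r] <- b
    networks[[r]] <- stage("network", build_network(matrices[[r]], beta = b))
    mods[[r]] <- stage("modules",
                       detect_modules(matrices[[r]], networks[[r]],
                                      min_size = config$min_size,
                                      merge_height = config$merge_height,
                                      cut_height = config$cut_height))
    out <- data.frame(gene = names(mods[[r]]$labels),
                      module = unname(mods[[r]]$labels),
                      stringsAsFactors = FALSE)
    if (!is.null(mods[[r]]$MM)) {
      own <- vapply(seq_len(nrow(out)), function(i)
        if (out$module[i] == UNASSIGNED) NA_real_
        else mods[[r]]$MM[out$gene[i], out$module[i]], numeric(1))
      out$own_mm <- own
      out$mm_quantile <- unname(mods[[r]]$mm_quantile[out$gene])
      utils::write.table(
        data.frame(sample_id = rownames(mods[[r]]$eigengenes),
                   mods[[r]]$eigengenes, check.names = FALSE),
        file.path(config$out_dir, paste0("eigengenes_", r, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(out,
                       file.path(config$out_dir, paste0("modules_", r, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  target <- vapply(regions, function(r) {
    lab <- mods[[r]]$labels
    if (!config$seed_gene %in% names(lab)) return(NA_character_)
    tm <- lab[[config$seed_gene]]
    if (tm == UNASSIGNED) NA_character_ else tm
  }, character(1))

  universe <- gene_ids(matrices[[1]])
  pairs <- utils::combn(regions, 2)
  n_pairs <- ncol(pairs)
  overlap <- NULL
  rows <- list()
  for (j in seq_len(n_pairs)) {
    ra <- pairs[1, j]; rb <- pairs[2, j]
    if (is.na(target[ra]) || is.na(target[rb])) next
    ga <- names(mods[[ra]]$labels)[mods[[ra]]$labels == target[ra]]
    gb <- names(mods[[rb]]$labels)[mods[[rb]]$labels == target[rb]]
    rows[[length(rows) + 1L]] <-
      overlap_stats(length(ga), length(gb), length(intersect(ga, gb)),
                    length(universe), bonferroni_n = n_pairs,
                    module_a = paste0(ra, ":", target[ra]),
                    module_b = paste0(rb, ":", target[rb]))
  }
  if (length(rows)) {
    overlap <- do.call(rbind, rows)
    utils::write.table(overlap, file.path(config$out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  pres <- NULL
  if (config$n_perm > 0 && !is.na(target[1]) && length(regions) > 1) {
    rows <- list()
    for (r in regions[-1]) {
      z <- stage("preservation", preservation_zsummary(
        list(matrix = matrices[[1]], network = networks[[1]]),
        list(matrix = matrices[[r]], network = networks[[r]]),
        mods[[1]]$labels, target[1],
        n_perm = config$n_perm, seed = config$seed))
      rows[[r]] <- data.frame(test_region = r, module = z$module,
                              z_density = z$z_density,
                              z_connectivity = z$z_connectivity,
                              z_summary = z$z_summary,
                              n_permutations = z$n_permutations)
    }
    pres <- do.call(rbind, rows)
    utils::write.table(pres, file.path(config$out_dir, "preservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  mm_list <- lapply(mods, `[[`, "MM")
  labels_list <- lapply(mods, `[[`, "labels")
  hubs <- stage("hubs", hub_genes(mm_list, labels_list, q = config$hub_q,
                                  min_regions = config$hub_min_regions))
  writeLines(hubs, file.path(config$out_dir, "hubs.txt"))
  core <- stage("core", core_set(mm_list, labels_list, unname(target),
                                 q = config$core_q))
  writeLines(core, file.path(config$out_dir, "core_set.txt"))

  enr <- NULL
  if (!is.null(config$gmt_path) && length(core)) {
    sets <- stage("enrichment", read_gmt(config$gmt_path))
    enr <- stage("enrichment", gene_set_enrichment(
      gene_set("core_set", core), sets, universe))
    utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  for (r in regions) {
    if (is.na(target[r])) next
    members <- names(mods[[r]]$labels)[mods[[r]]$labels == target[r]]
    nb <- stage("neighborhood", tom_neighbors(networks[[r]]$tom, members,
                                              config$seed_gene,
                                              threshold = config$tom_min))
    utils::write.table(nb$edges,
                       file.path(config$out_dir, paste0("edges_", r, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  prof <- NULL
  if (length(regions) > 1 && "individual" %in% names(matrices[[1]]$metadata)) {
    rows <- list()
    for (j in seq_len(n_pairs)) {
      rc <- tryCatch(region_contrast(unname(matrices), config$seed_gene,
                                     pairs[1, j], pairs[2, j]),
                     error = function(e) NULL)
      if (!is.null(rc)) rows[[length(rows) + 1L]] <- as.data.frame(rc)
    }
    if (length(rows)) {
      prof <- do.call(rbind, rows)
      utils::write.table(prof, file.path(config$out_dir, "profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    parameters = unclass(config)[c("beta", "pick_power", "r2_cut", "min_size",
                                   "merge_height", "tom_min", "hub_q",
                                   "hub_min_regions", "core_q", "n_perm",
                                   "iac_sd", "seed")],
    regions = regions,
    selected_beta = as.list(betas),
    n_genes_after_filter = length(universe),
    n_modules = lapply(mods, function(m)
      length(setdiff(unique(m$labels), UNASSIGNED))),
    target_module = as.list(target),
    target_module_size = lapply(regions, function(r)
      if (is.na(target[r])) 0L else sum(mods[[r]]$labels == target[r])),
    n_hubs = length(hubs),
    core_set_size = length(core))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(matrices = matrices, networks = networks, modules = mods,
                 target_modules = target, hubs = hubs, core = core,
                 preservation = pres, overlap = overlap, enrichment = enr,
                 profile = prof, manifest = manifest))
}
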