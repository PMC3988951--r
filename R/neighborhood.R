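#' TOM-threshold neighbourhood of a seed gene within a module
#'
#' Induces the graph on the module's genes whose edges have topological
#' overlap strictly greater than `threshold` (default 0.10), and reports the
#' seed gene's direct neighbours and connected component.
#'
#' @param tom Symmetric TOM matrix with gene ids as dimnames.
#' @param module_genes Character vector of module member ids.
#' @param seed Seed gene id (must be in `module_genes`).
#' @param threshold Edge threshold; an edge exactly at the threshold is
#'   excluded (default 0.10).
#' @return List: `edges` (data frame `gene_a`, `gene_b`, `tom`, each
#'   undirected pair once, `gene_a < gene_b`), `threshold`, `seed_gene`,
#'   `direct_neighbors` (sorted), `seed_component` (genes reachable from the
#'   seed, including it).
#' @export
tom_neighbors <- function(tom, module_genes, seed, threshold = 0.10) {
  if (!seed %in% module_genes) stop("seed gene not in module_genes")
  if (!all(module_genes %in% rownames(tom)))
    stop("module genes missing from the TOM")
  sub <- tom[module_genes, module_genes, drop = FALSE]
  idx <- which(upper.tri(sub) & sub > threshold, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = pmin(module_genes[idx[, 1]], module_genes[idx[, 2]]),
    gene_b = pmax(module_genes[idx[, 1]], module_genes[idx[, 2]]),
    tom = sub[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nbrs <- sort(unique(c(edges$gene_b[edges$gene_a == seed],
                        edges$gene_a[edges$gene_b == seed])))
  # connected component of the seed by breadth-first expansion
  comp <- seed
  frontier <- seed
  while (length(frontier)) {
    nxt <- unique(c(edges$gene_b[edges$gene_a %in% frontier],
                    edges$gene_a[edges$gene_b %in% frontier]))
    frontier <- setdiff(nxt, comp)
    comp <- c(comp, frontier)
  }
  list(edges = edges, threshold = threshold, seed_gene = seed,
       direct_neighbors = nbrs, seed_component = sort(comp))
}

#' Module-membership profile of marker genes across regions
#'
#' For each marker and region, reports the marker's own-module MM within the
#' region's target module, or 0 when the marker is not a member of that
#' module there (so undetected markers show as 0). Rows are ordered by
#' average-linkage hierarchical clustering on Euclidean distance of the MM
#' profiles.
#'
#' @param mm_list List of genes x modules MM matrices, one per region.
#' @param labels_list List of gene -> module vectors, one per region.
#' @param target_modules Character vector naming the target module per
#'   region (`NA` skips a region's membership, leaving 0s).
#' @param markers A [gene_set()] of marker genes.
#' @param region_names Optional column names (defaults to `names(mm_list)`).
#' @return List: `profile` (markers x regions matrix, rows in clustered
#'   order), `row_order` (marker ids in display order).
#' @export
marker_mm_profile <- function(mm_list, labels_list, target_modules, markers,
                              region_names = NULL) {
  stopifnot(length(mm_list) >= 1,
            length(mm_list) == length(labels_list),
            length(target_modules) == length(mm_list))
  if (is.null(region_names)) region_names <- names(mm_list)
  if (is.null(region_names)) region_names <- paste0("R", seq_along(mm_list))
  prof <- matrix(0, length(markers$genes), length(mm_list),
                 dimnames = list(markers$genes, region_names))
  for (i in seq_along(mm_list)) {
    tm <- target_modules[i]
    if (is.na(tm)) next
    lab <- labels_list[[i]]
    members <- names(lab)[lab == tm]
    hit <- intersect(markers$genes, members)
    if (length(hit)) prof[hit, i] <- mm_list[[i]][hit, tm]
  }
  if (all(prof == 0))
    warning("no marker is a member of any region's target module")
  ord <- rownames(prof)
  if (nrow(prof) > 2) {
    hc <- stats::hclust(stats::dist(prof), method = "average")
    ord <- rownames(prof)[hc$order]
  }
  list(profile = prof[ord, , drop = FALSE], row_order = ord)
}
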