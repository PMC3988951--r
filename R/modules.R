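#' Average-linkage gene dendrogram from a dissimilarity matrix
#'
#' Standard agglomerative (UPGMA) tree over genes, typically on the TOM
#' dissimilarity `1 - TOM`.
#'
#' @param dissimilarity Symmetric non-negative matrix with zero diagonal and
#'   gene ids as dimnames.
#' @return An object of class `hclust`.
#' @export
hierarchical_tree <- function(dissimilarity) {
  assert_symmetric(dissimilarity, what = "dissimilarity")
  if (any(dissimilarity < 0)) stop("dissimilarity must be non-negative")
  if (any(abs(diag(dissimilarity)) > 1e-10))
    stop("dissimilarity must have zero diagonal")
  if (is.null(rownames(dissimilarity)))
    stop("dissimilarity needs gene ids as dimnames")
  tree <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  # ties can leave float-level monotonicity violations that break cutree
  viol <- tree$height - cummax(tree$height)
  if (min(viol) < -1e-8) stop("non-monotone merge heights")
  tree$height <- cummax(tree$height)
  tree
}

#' Decompose a dendrogram into modules (tree-variant dynamic cut)
#'
#' Top-down, height-guided branch decomposition. Branches of the tree lying
#' entirely below `cut_height` are candidate modules. Each candidate is then
#' analysed recursively: if the sorted sequence of its internal merge
#' heights shows a pronounced jump in its upper half (a gap wider than 15%
#' of the branch's height range), the branch is split at that jump, so that
#' leaves or small sub-branches joining at outlying heights (typically noise
#' genes attaching just below the cut, or two distinct modules joined by a
#' weak bridge) are separated, while a homogeneous branch stays intact.
#' Resulting sub-branches with at least `min_size` leaves become modules
#' (labelled `M1`, `M2`, ... in decreasing size order); all other genes are
#' labelled `"unassigned"`. If splitting a candidate leaves no sub-branch of
#' `min_size`, the whole candidate is kept as one module. Deterministic for
#' fixed input.
#'
#' @param tree An `hclust` object from [hierarchical_tree()].
#' @param min_size Minimum module size (default 30; must be >= 2).
#' @param cut_height Height below which branches are decomposed; defaults to
#'   99% of the maximal merge height.
#' @return Named character vector gene -> module label.
#' @export
dynamic_tree_cut <- function(tree, min_size = 30, cut_height = NULL) {
  if (min_size < 2) stop("min_size must be >= 2")
  stopifnot(inherits(tree, "hclust"))
  if (is.null(cut_height)) cut_height <- 0.99 * max(tree$height)
  merge <- tree$merge
  height <- tree$height
  leaves <- tree$labels
  # leaf sets and subtree-node sets per internal node
  node_leaves <- vector("list", nrow(merge))
  node_desc <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    lv <- character(); ds <- i
    for (k in merge[i, ]) {
      if (k < 0) lv <- c(lv, leaves[-k])
      else { lv <- c(lv, node_leaves[[k]]); ds <- c(ds, node_desc[[k]]) }
    }
    node_leaves[[i]] <- lv
    node_desc[[i]] <- ds
  }
  # maximal subtrees (node ids; negative = leaf) with top height <= thr
  decompose <- function(root, thr) {
    if (height[root] <= thr) return(root)
    out <- integer()
    for (k in merge[root, ]) {
      if (k < 0) out <- c(out, k)
      else out <- c(out, decompose(k, thr))
    }
    out
  }
  # recursive split at the most pronounced upper-half jump of the branch's
  # internal merge-height sequence
  analyze <- function(node) {
    hb <- sort(height[node_desc[[node]]])
    m <- length(hb)
    if (m < 4) return(list(node_leaves[[node]]))
    med <- stats::median(hb)
    upper <- which(hb >= med & seq_len(m) < m)
    if (!length(upper)) return(list(node_leaves[[node]]))
    gaps <- hb[upper + 1] - hb[upper]
    i <- upper[which.max(gaps)]
    if (hb[m] - hb[1] <= 0 || max(gaps) <= 0.15 * (hb[m] - hb[1]))
      return(list(node_leaves[[node]]))
    thr <- (hb[i] + hb[i + 1]) / 2
    parts <- decompose(node, thr)
    out <- list()
    for (p in parts)
      if (p > 0 && length(node_leaves[[p]]) >= min_size)
        out <- c(out, analyze(p))
    if (!length(out)) return(list(node_leaves[[node]]))
    out
  }

  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  cand <- names(sizes)[sizes >= min_size]
  cand <- cand[order(-sizes[cand], as.integer(cand))]

  modules <- list()
  for (b in cand) {
    genes <- names(cl)[cl == as.integer(b)]
    # the branch is a subtree: its root is the node whose leaf set equals it
    root <- which(vapply(node_leaves, function(lv)
      length(lv) == length(genes) && all(lv %in% genes), logical(1)))[1]
    modules <- c(modules, analyze(root))
  }
  modules <- modules[order(-lengths(modules))]
  labels <- stats::setNames(rep(UNASSIGNED, length(leaves)), leaves)
  for (i in seq_along(modules))
    labels[modules[[i]]] <- paste0("M", i)
  labels
}

#' Module eigengenes and proportion of variance explained
#'
#' For each module, member genes are standardized (mean 0, SD 1 across
#' samples) and the module eigengene (ME) is the first right singular vector
#' of the standardized module matrix: a unit-norm per-sample summary profile.
#' The sign is fixed so the ME correlates non-negatively with the module's
#' mean standardized profile.
#'
#' @param matrix An [expression_matrix()].
#' @param labels Named gene -> module vector; `"unassigned"` is skipped.
#' @return List: `eigengenes` (samples x modules matrix, unit-norm columns),
#'   `prop_var_explained` (named vector in `[0, 1]`).
#' @export
module_eigengenes <- function(matrix, labels) {
  mods <- setdiff(unique(labels), UNASSIGNED)
  if (!length(mods)) stop("no modules in labels")
  n <- ncol(matrix$values)
  E <- matrix(NA_real_, n, length(mods),
              dimnames = list(sample_ids(matrix), mods))
  pv <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    g <- names(labels)[labels == m]
    if (length(g) < 2) stop("module ", m, " has fewer than 2 genes")
    X <- matrix$values[g, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) stop("zero-variance gene in module ", m)
    Xs <- (X - rowMeans(X)) / sds
    sv <- svd(Xs, nu = 0, nv = 1)
    me <- sv$v[, 1]
    if (sum(colMeans(Xs) * me) < 0) me <- -me
    E[, m] <- me
    pv[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, prop_var_explained = pv)
}

#' Merge modules with highly correlated eigengenes
#'
#' Average-linkage clustering of module eigengenes under dissimilarity
#' `1 - cor(ME_i, ME_j)`; clusters joining strictly below `merge_height`
#' are unioned (the merged module keeps the label of its largest
#' constituent), MEs are recomputed, and the procedure repeats until no pair
#' of MEs has dissimilarity below `merge_height`. The default 0.1
#' corresponds to merging modules whose eigengenes correlate above 0.9.
#'
#' @param matrix An [expression_matrix()].
#' @param labels Named gene -> module vector.
#' @param merge_height ME-dendrogram height cut (default 0.1).
#' @return List: `labels` (merged), `eigengenes`, `prop_var_explained`.
#' @export
merge_close_modules <- function(matrix, labels, merge_height = 0.1) {
  repeat {
    mods <- setdiff(unique(labels), UNASSIGNED)
    if (length(mods) < 2) break
    me <- module_eigengenes(matrix, labels)
    d <- 1 - stats::cor(me$eigengenes)
    if (min(upper_vals(d)) >= merge_height) break
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    # strict "<": a pair at exactly merge_height is not merged
    grp <- stats::cutree(hc, h = merge_height - 1e-12)
    if (max(grp) == length(mods)) break
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      if (length(members) < 2) next
      sizes <- vapply(members, function(m) sum(labels == m), integer(1))
      keep <- members[which.max(sizes)]
      labels[labels %in% members] <- keep
    }
  }
  me <- module_eigengenes(matrix, labels)
  list(labels = labels, eigengenes = me$eigengenes,
       prop_var_explained = me$prop_var_explained)
}

#' Module membership (kME) of every gene for every module
#'
#' `MM[g, m]` is the Pearson correlation between gene `g`'s expression
#' profile and the eigengene of module `m`; it ranges from -1 (perfect
#' anti-correlation) to 1 and quantifies how strongly a gene "belongs" to a
#' module, whether or not it is an assigned member.
#'
#' @param matrix An [expression_matrix()].
#' @param eigengenes Samples x modules ME matrix from [module_eigengenes()].
#' @return Genes x modules matrix of correlations.
#' @export
module_membership <- function(matrix, eigengenes) {
  if (nrow(eigengenes) != ncol(matrix$values))
    stop("eigengene samples do not match the expression matrix")
  stats::cor(t(matrix$values), eigengenes)
}

#' Within-module membership quantile of one gene
#'
#' Module members are ranked by their own-module MM in decreasing order
#' (ties broken by gene id) and the gene's quantile is `1 - rank / size`:
#' the top-ranked member of a 100-gene module sits at 0.99, the bottom one
#' at 0. Hub status is conventionally MM quantile >= 0.90.
#'
#' @param MM Genes x modules membership matrix.
#' @param labels Named gene -> module vector.
#' @param gene Gene id (must be a member of `module`).
#' @param module Module label.
#' @return Quantile in `[0, 1)`.
#' @export
mm_quantile <- function(MM, labels, gene, module) {
  members <- names(labels)[labels == module]
  if (!gene %in% members) stop(gene, " is not a member of ", module)
  q <- mm_quantiles(MM, labels)
  unname(q[gene])
}

#' Own-module membership quantiles for all assigned genes
#'
#' Vectorised form of [mm_quantile()]: every assigned gene's quantile within
#' its own module; unassigned genes get `NA`.
#'
#' @inheritParams mm_quantile
#' @return Named numeric vector over all genes in `labels`.
#' @export
mm_quantiles <- function(MM, labels) {
  out <- stats::setNames(rep(NA_real_, length(labels)), names(labels))
  for (m in setdiff(unique(labels), UNASSIGNED)) {
    members <- names(labels)[labels == m]
    mm <- MM[members, m]
    ord <- order(-mm, members)           # stable: (-MM, gene id)
    rank <- match(members, members[ord])
    out[members] <- 1 - rank / length(members)
  }
  out
}

#' Hub genes across regional networks
#'
#' Genes whose own-module membership quantile is at least `q` in at least
#' `min_regions` regions — the most central members, candidates for driving
#' module function.
#'
#' @param mm_list List (one per region) of genes x modules MM matrices
#'   (`NULL` entries, e.g. regions without modules, are skipped).
#' @param labels_list List (one per region) of gene -> module vectors.
#' @param q Quantile cut (default 0.90, the "top 90th quantile" hub rule).
#' @param min_regions Minimum number of regions (default 5).
#' @return Character vector of hub gene ids (sorted).
#' @export
hub_genes <- function(mm_list, labels_list, q = 0.90, min_regions = 5) {
  stopifnot(length(mm_list) == length(labels_list))
  if (length(mm_list) < min_regions)
    return(character())
  counts <- list()
  for (i in seq_along(mm_list)) {
    if (is.null(mm_list[[i]])) next
    quant <- mm_quantiles(mm_list[[i]], labels_list[[i]])
    hubs <- names(quant)[!is.na(quant) & quant >= q]
    for (g in hubs) counts[[g]] <- (counts[[g]] %||% 0L) + 1L
  }
  sort(names(counts)[vapply(counts, function(x) x >= min_regions, logical(1))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Core gene set of a target module across regions
#'
#' Union over regions of target-module members with own-module membership
#' quantile strictly above `q` (default 0.80) — the consistently central
#' portion of the module.
#'
#' @param mm_list List of MM matrices, one per region.
#' @param labels_list List of gene -> module vectors, one per region.
#' @param target_modules Character vector (one per region) naming the target
#'   module in that region, or `NA` to skip a region.
#' @param q Quantile cut (default 0.80).
#' @return Sorted character vector of core gene ids.
#' @export
core_set <- function(mm_list, labels_list, target_modules, q = 0.80) {
  stopifnot(length(mm_list) == length(labels_list),
            length(target_modules) == length(labels_list))
  out <- character()
  for (i in seq_along(mm_list)) {
    tm <- target_modules[i]
    if (is.na(tm) || is.null(mm_list[[i]])) next
    if (!tm %in% labels_list[[i]]) {
      warning("target module ", tm, " absent in region ", i, "; skipped")
      next
    }
    quant <- mm_quantiles(mm_list[[i]], labels_list[[i]])
    members <- names(labels_list[[i]])[labels_list[[i]] == tm]
    out <- union(out, members[quant[members] > q])
  }
  sort(out)
}

#' Detect, merge and characterise modules for one region
#'
#' Convenience wrapper running the full per-region module stage: TOM
#' dissimilarity tree, tree-variant dynamic cut, eigengene merging, and
#' module membership.
#'
#' @param matrix An [expression_matrix()].
#' @param network A `coexpression_network` from [build_network()].
#' @param min_size Minimum module size (default 30).
#' @param merge_height ME merge height (default 0.1).
#' @param cut_height Dendrogram cut height (default 99% of max height).
#' @return List: `labels`, `eigengenes`, `prop_var_explained`, `MM`,
#'   `mm_quantile` (own-module quantiles), `tree`.
#' @export
detect_modules <- function(matrix, network, min_size = 30, merge_height = 0.1,
                           cut_height = NULL) {
  diss <- 1 - network$tom
  diag(diss) <- 0
  tree <- hierarchical_tree(diss)
  labels <- dynamic_tree_cut(tree, min_size = min_size, cut_height = cut_height)
  if (all(labels == UNASSIGNED))
    return(list(labels = labels, eigengenes = NULL, prop_var_explained = NULL,
                MM = NULL, mm_quantile = NULL, tree = tree))
  merged <- merge_close_modules(matrix, labels, merge_height = merge_height)
  MM <- module_membership(matrix, merged$eigengenes)
  list(labels = merged$labels,
       eigengenes = merged$eigengenes,
       prop_var_explained = merged$prop_var_explained,
       MM = MM,
       mm_quantile = mm_quantiles(MM, merged$labels),
       tree = tree)
}
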