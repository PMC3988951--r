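#' Overlap statistics for one pair of modules
#'
#' Cross-tabulation cell: counts, percentages relative to each module, the
#' overlap expected by chance, and the one-sided hypergeometric upper-tail
#' p-value `P[X >= overlap]` for drawing `size_b` genes from a universe
#' containing `size_a` marked genes.
#'
#' @param size_a,size_b Module sizes.
#' @param overlap Observed overlap (`<= min(size_a, size_b)`).
#' @param universe Size of the shared gene universe.
#' @param bonferroni_n Number of tests the 0.05 level is divided by
#'   (default 1).
#' @param module_a,module_b Optional labels.
#' @return One-row data frame: `module_a`, `module_b`, `size_a`, `size_b`,
#'   `overlap`, `universe`, `pct_of_a`, `pct_of_b` (percent), `expected`,
#'   `p_value`, `bonferroni_n`, `significant`.
#' @export
overlap_stats <- function(size_a, size_b, overlap, universe,
                          bonferroni_n = 1, module_a = "A", module_b = "B") {
  if (universe < 1) stop("empty universe")
  if (overlap > min(size_a, size_b) || size_a > universe || size_b > universe)
    stop("inconsistent counts")
  p <- stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                     lower.tail = FALSE)
  data.frame(module_a = module_a, module_b = module_b,
             size_a = size_a, size_b = size_b, overlap = overlap,
             universe = universe,
             pct_of_a = 100 * overlap / size_a,
             pct_of_b = 100 * overlap / size_b,
             expected = size_a * size_b / universe,
             p_value = p,
             bonferroni_n = bonferroni_n,
             significant = p < 0.05 / bonferroni_n,
             stringsAsFactors = FALSE)
}

#' Cross-tabulation of two module assignments
#'
#' For every pair of modules (one from each labeling, `"unassigned"`
#' excluded) computes [overlap_stats()] on the shared gene universe, with a
#' one-sided hypergeometric test and a Bonferroni flag.
#'
#' @param labels_a,labels_b Named gene -> module vectors defined on
#'   `universe`.
#' @param universe Character vector of gene ids both labelings cover.
#' @param bonferroni_n Bonferroni denominator; defaults to the number of
#'   module pairs tested.
#' @return Data frame with one row per module pair (columns as in
#'   [overlap_stats()]).
#' @export
module_overlap_table <- function(labels_a, labels_b, universe,
                                 bonferroni_n = NULL) {
  if (!length(universe)) stop("empty universe")
  if (!all(universe %in% names(labels_a)) || !all(universe %in% names(labels_b)))
    stop("labelings must cover the universe")
  la <- labels_a[universe]
  lb <- labels_b[universe]
  mods_a <- setdiff(unique(la), UNASSIGNED)
  mods_b <- setdiff(unique(lb), UNASSIGNED)
  if (is.null(bonferroni_n)) bonferroni_n <- length(mods_a) * length(mods_b)
  rows <- list()
  for (ma in mods_a) for (mb in mods_b) {
    ga <- universe[la == ma]
    gb <- universe[lb == mb]
    rows[[length(rows) + 1L]] <-
      overlap_stats(length(ga), length(gb), length(intersect(ga, gb)),
                    length(universe), bonferroni_n, ma, mb)
  }
  do.call(rbind, rows)
}

# the 7 preservation statistics of a gene set, reference vs test
preservation_stats <- function(set, ref, test) {
  cr <- ref$network$cor[set, set]
  ct <- test$network$cor[set, set]
  at <- test$network$adjacency[set, set]
  ar <- ref$network$adjacency[set, set]

  me_of <- function(mat, genes) {
    X <- mat$values[genes, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    Xs <- (X - rowMeans(X)) / sds
    sv <- svd(Xs, nu = 0, nv = 1)
    me <- sv$v[, 1]
    if (sum(colMeans(Xs) * me) < 0) me <- -me
    list(me = me, propvar = sv$d[1]^2 / sum(sv$d^2))
  }
  ref_me <- me_of(ref$matrix, set)
  test_me <- me_of(test$matrix, set)
  kme_ref <- as.vector(stats::cor(t(ref$matrix$values[set, , drop = FALSE]),
                                  ref_me$me))
  kme_test <- as.vector(stats::cor(t(test$matrix$values[set, , drop = FALSE]),
                                   test_me$me))
  kim_ref <- rowSums(ar) - diag(ar)
  kim_test <- rowSums(at) - diag(at)

  c(meanCor = mean(upper_vals(ct)),
    meanAdj = mean(upper_vals(at)),
    propVarExplained = test_me$propvar,
    meanSignAwareKME = mean(sign(kme_ref) * kme_test),
    cor_kIM = stats::cor(kim_ref, kim_test),
    cor_kME = stats::cor(kme_ref, kme_test),
    cor_cor = stats::cor(upper_vals(cr), upper_vals(ct)))
}

#' Permutation Zsummary module preservation
#'
#' Quantifies how well a module found in a reference dataset is preserved in
#' a test dataset. Observed statistics are computed on the module's genes:
#' density statistics (mean correlation, mean adjacency, proportion of
#' variance explained by the test-data eigengene, mean sign-aware kME) ask
#' whether the genes remain densely connected in the test network;
#' connectivity statistics (reference-vs-test correlations of intramodular
#' connectivity, of kME, and of the vectorized correlation sub-matrices) ask
#' whether the connectivity pattern is similar. A permutation null draws
#' `n_perm` random same-size gene sets from the test universe; each
#' statistic is standardized as `Z = (obs - mean_perm) / sd_perm`, and the
#' composite is `Zsummary = (median(density Z) + median(connectivity Z)) /
#' 2`. Interpretation bands: below 2, no evidence of preservation; above 5,
#' moderate; above 10, strong.
#'
#' @param ref,test Lists with elements `matrix` (an [expression_matrix()])
#'   and `network` (a `coexpression_network`), sharing the gene universe.
#' @param labels_ref Named gene -> module vector for the reference.
#' @param module Module label to evaluate.
#' @param n_perm Number of permutations (default 100, minimum 20).
#' @param seed Integer RNG seed.
#' @return A `preservation_z` list: `module`, `stats_observed`,
#'   `z_per_stat`, `z_density`, `z_connectivity`, `z_summary`,
#'   `n_permutations`, `seed`.
#' @export
preservation_zsummary <- function(ref, test, labels_ref, module,
                                  n_perm = 100, seed = 1L) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  set <- names(labels_ref)[labels_ref == module]
  universe <- intersect(ref$network$gene_ids, test$network$gene_ids)
  if (!all(set %in% universe)) stop("module genes absent from a network")
  if (length(set) < 3) stop("module too small for preservation statistics")

  obs <- preservation_stats(set, ref, test)
  set.seed(seed)
  perm <- matrix(NA_real_, n_perm, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_perm)) {
    rs <- sample(universe, length(set))
    perm[i, ] <- preservation_stats(rs, ref, test)
  }
  mu <- colMeans(perm)
  sdv <- apply(perm, 2, stats::sd)
  z <- (obs - mu) / sdv
  drop <- !is.finite(z)
  if (any(drop)) {
    warning("degenerate permutation SD; dropping: ",
            paste(names(z)[drop], collapse = ", "))
    z <- z[!drop]
  }
  dens_names <- intersect(c("meanCor", "meanAdj", "propVarExplained",
                            "meanSignAwareKME"), names(z))
  conn_names <- intersect(c("cor_kIM", "cor_kME", "cor_cor"), names(z))
  z_density <- stats::median(z[dens_names])
  z_connectivity <- stats::median(z[conn_names])
  structure(list(module = module,
                 stats_observed = obs,
                 z_per_stat = z,
                 z_density = z_density,
                 z_connectivity = z_connectivity,
                 z_summary = (z_density + z_connectivity) / 2,
                 n_permutations = n_perm,
                 seed = seed),
            class = "preservation_z")
}

#' @export
print.preservation_z <- function(x, ...) {
  cat(sprintf(
    "preservation_z: module %s, Zsummary = %.2f (density %.2f, connectivity %.2f), %d permutations\n",
    x$module, x$z_summary, x$z_density, x$z_connectivity, x$n_permutations))
  invisible(x)
}
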