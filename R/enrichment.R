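#' Construct a gene set
#'
#' @param name Set label.
#' @param genes Character vector of gene ids (de-duplicated with a warning).
#' @param source Free-text provenance.
#' @return A `gene_set` list.
#' @export
gene_set <- function(name, genes, source = "") {
  if (!length(genes)) stop("gene set must be non-empty")
  if (anyDuplicated(genes)) {
    warning("duplicate genes in set '", name, "' de-duplicated")
    genes <- unique(genes)
  }
  structure(list(name = name, genes = as.character(genes), source = source),
            class = "gene_set")
}

#' Restrict gene sets to an analysis universe
#'
#' Intersects each set with the universe of genes actually analysed; sets
#' left empty are dropped with a warning.
#'
#' @param sets List of [gene_set()] objects.
#' @param universe Character vector of gene ids.
#' @return List of restricted `gene_set` objects.
#' @export
restrict_to_universe <- function(sets, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  out <- list()
  for (s in sets) {
    g <- intersect(s$genes, universe)
    if (!length(g)) {
      warning("set '", s$name, "' has no genes in the universe; dropped")
      next
    }
    out[[length(out) + 1L]] <- gene_set(s$name, g, s$source)
  }
  out
}

#' Chi-square test with Yates continuity correction on a 2x2 table
#'
#' Statistic `sum((max(0, |O - E| - 0.5))^2 / E)` over the four cells, with
#' expected counts from the marginals; p-value from the upper tail of
#' chi-square with 1 df. The continuity correction is floored at 0 so a
#' table exactly at independence scores 0 (set `floor_correction = FALSE`
#' for the classical uncapped form).
#'
#' @param table 2x2 matrix of counts with strictly positive marginals.
#' @param floor_correction Floor `|O - E| - 0.5` at 0 (default TRUE).
#' @return List: `statistic`, `p_value`.
#' @export
chisq_yates <- function(table, floor_correction = TRUE) {
  if (!is.matrix(table) || !all(dim(table) == 2))
    stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal")
  E <- outer(rs, cs) / sum(table)
  d <- abs(table - E) - 0.5
  if (floor_correction) d <- pmax(d, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Over-representation of gene sets in a query list
#'
#' For each annotation set (restricted to the universe), tests whether the
#' query list contains more of its genes than expected by chance: one-sided
#' hypergeometric p, chi-square with Yates correction, expected overlap, and
#' Bonferroni correction over the number of sets tested.
#'
#' @param query A [gene_set()] (e.g. a module or core set), subset of
#'   `universe`.
#' @param sets List of [gene_set()] annotation sets.
#' @param universe Character vector of background gene ids.
#' @return Data frame, one row per set: `set_name`, `query_size`,
#'   `set_size_in_universe`, `overlap`, `universe`, `expected`, `fisher_p`,
#'   `chi2_yates`, `chi2_p`, `bonferroni_p`.
#' @export
gene_set_enrichment <- function(query, sets, universe) {
  if (!all(query$genes %in% universe))
    stop("query must be a subset of the universe")
  sets <- restrict_to_universe(sets, universe)
  n <- length(universe)
  q <- length(query$genes)
  rows <- lapply(sets, function(s) {
    k <- length(s$genes)
    ov <- length(intersect(query$genes, s$genes))
    fisher_p <- stats::phyper(ov - 1, k, n - k, q, lower.tail = FALSE)
    tab <- matrix(c(ov, q - ov, k - ov, n - q - k + ov), 2, 2)
    chi <- tryCatch(chisq_yates(tab),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    data.frame(set_name = s$name, query_size = q, set_size_in_universe = k,
               overlap = ov, universe = n, expected = q * k / n,
               fisher_p = fisher_p, chi2_yates = chi$statistic,
               chi2_p = chi$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- pmin(1, out$fisher_p * nrow(out))
  out
}

#' Collapse redundant gene sets by Jaccard similarity
#'
#' Single-linkage grouping: sets whose pairwise Jaccard index reaches
#' `jaccard_min` are chained into one group, and the largest set of each
#' group is kept as its representative.
#'
#' @param sets List of [gene_set()] objects.
#' @param jaccard_min Jaccard threshold (default 0.5).
#' @return List: `representatives` (list of `gene_set`), `groups` (data
#'   frame: `set_name`, `group`, `representative`).
#' @export
collapse_redundant_sets <- function(sets, jaccard_min = 0.5) {
  if (!length(sets)) stop("need at least one set")
  n <- length(sets)
  group <- seq_len(n)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sets[[i]]$genes; b <- sets[[j]]$genes
    jac <- length(intersect(a, b)) / length(union(a, b))
    if (jac >= jaccard_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) group[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  gid <- match(root, unique(root))
  reps <- lapply(unique(gid), function(g) {
    members <- which(gid == g)
    sizes <- vapply(members, function(i) length(sets[[i]]$genes), integer(1))
    sets[[members[which.max(sizes)]]]
  })
  groups <- data.frame(
    set_name = vapply(sets, function(s) s$name, character(1)),
    group = gid,
    representative = vapply(gid, function(g) reps[[g]]$name, character(1)),
    stringsAsFactors = FALSE)
  list(representatives = reps, groups = groups)
}
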