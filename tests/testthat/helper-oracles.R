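# Brute-force oracles and small fixtures shared across tests.

# Winsorized mean by explicit sort/clip/average
oracle_winsor <- function(x, lq, uq) {
  q <- stats::quantile(x, c(lq, uq), names = FALSE, type = 7)
  y <- x
  y[y < q[1]] <- q[1]
  y[y > q[2]] <- q[2]
  mean(y)
}

# TOM by direct evaluation of the formula with nested loops
oracle_tom <- function(a) {
  n <- nrow(a)
  ad <- a
  diag(ad) <- 0
  k <- rowSums(ad)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + ad[i, u] * ad[u, j]
    out[i, j] <- (s + ad[i, j]) / (min(k[i], k[j]) + 1 - ad[i, j])
  }
  out
}

# average-linkage agglomeration, naive O(n^3); returns sorted merge heights
oracle_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric()
  avg_dist <- function(c1, c2) mean(d[c1, c2])
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      dd <- avg_dist(clusters[[i]], clusters[[j]])
      if (dd < bd) { bd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# hypergeometric upper tail P[X >= ov] by exhaustive enumeration of draws
oracle_hyper_enum <- function(size_a, size_b, ov, universe) {
  marked <- seq_len(size_a)
  draws <- utils::combn(universe, size_b)
  hits <- apply(draws, 2, function(dr) sum(dr %in% marked) >= ov)
  mean(hits)
}

# hypergeometric upper tail by explicit probability-mass summation
oracle_hyper_sum <- function(size_a, size_b, ov, universe) {
  ks <- ov:min(size_a, size_b)
  sum(stats::dhyper(ks, size_a, universe - size_a, size_b))
}

# chi-square with Yates correction by direct arithmetic
oracle_chisq_yates <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
}

# random symmetric adjacency with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# random dissimilarity (symmetric, zero diagonal) with gene-id dimnames
random_dissimilarity <- function(n) {
  d <- matrix(stats::runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  d
}

# quick expr_matrix from a bare matrix
quick_em <- function(vals, region = "R01", metadata = NULL) {
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- sprintf("s%03d", seq_len(ncol(vals)))
  expression_matrix(vals, region = region, metadata = metadata)
}

# small two-region simulation with one shared planted module
shared_module_sim <- function(n_genes = 400, n_samples = 60, mod_size = 60,
                              loading = c(0.6, 0.9), seed = 1, n_regions = 2) {
  cfg <- sim_config(n_regions = n_regions, n_samples_per_region = n_samples,
                    n_genes = n_genes,
                    modules = list(module_spec(mod_size, loading,
                                               seq_len(n_regions))),
                    seed = seed)
  generate_multiregion_dataset(cfg)
}
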