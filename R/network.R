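#' Signed adjacency from a correlation matrix
#'
#' The signed weighted-network transform `a_ij = ((1 + cor_ij) / 2) ^ beta`:
#' perfectly correlated pairs get weight 1, perfectly anti-correlated pairs
#' weight 0, and uncorrelated pairs `(1/2)^beta` (2.4e-4 at the default
#' beta = 12), so only positive co-expression carries appreciable weight.
#'
#' @param cor Symmetric correlation matrix, entries in `[-1, 1]`, diagonal 1.
#' @param beta Positive integer soft-thresholding power (default 12).
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(cor, beta = 12) {
  if (beta < 1) stop("beta must be >= 1")
  assert_symmetric(cor, what = "correlation matrix")
  if (min(cor) < -1 - 1e-8 || max(cor) > 1 + 1e-8)
    stop("correlations must lie in [-1, 1]")
  a <- ((1 + cor) / 2)^beta
  a[a > 1] <- 1
  diag(a) <- 1
  a
}

#' Whole-network connectivity (degree)
#'
#' @param adjacency Adjacency matrix (diagonal excluded from the sums).
#' @return Per-gene connectivity `k_i = sum_{j != i} a_ij`, named by gene.
#' @export
connectivity <- function(adjacency) {
  assert_symmetric(adjacency, what = "adjacency")
  rowSums(adjacency) - diag(adjacency)
}

#' Topological overlap matrix
#'
#' Pairwise similarity combining direct adjacency with shared-neighbour
#' weight:
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `TOM_ii = 1`. When both genes are isolated (`min k = 0`) the ratio
#' reduces to the direct adjacency, which is then necessarily 0.
#'
#' @param adjacency Symmetric adjacency in `[0, 1]`, diagonal 1.
#' @return Symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  assert_symmetric(adjacency, what = "adjacency")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a                       # sum_u a_iu a_uj, u != i,j by diag 0
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  (tom + t(tom)) / 2
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivity into `n_bins` equal-width bins, then regresses
#' log10(frequency) on log10(mean connectivity) over the non-empty bins.
#' The returned `r2` carries the sign `-sign(slope)`, so a decreasing
#' power-law-like distribution yields a positive value.
#'
#' @param connectivity_k Non-negative per-gene connectivities.
#' @param n_bins Number of equal-width bins (default 10).
#' @return A `scale_free_fit` list: `r2` (signed), `slope`, `mean_k`,
#'   `n_bins` (usable bins).
#' @export
scale_free_fit <- function(connectivity_k, n_bins = 10) {
  k <- connectivity_k
  if (any(k < 0)) stop("connectivity must be non-negative")
  if (diff(range(k)) == 0)
    stop("degenerate connectivity: fewer than 5 usable bins")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  use <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(use) < 5) stop("fewer than 5 usable bins")
  fit <- stats::lm(log10(freq[use]) ~ log10(kmean[use]))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(r2 = -sign(slope) * r2, slope = slope,
                 mean_k = mean(k), n_bins = sum(use)),
            class = "scale_free_fit")
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' Evaluates the signed scale-free fit index for each candidate power and
#' returns the smallest power whose signed r2 reaches `r2_cut`; if none
#' does, the power with the maximal r2 is returned with `reached_cut =
#' FALSE`.
#'
#' @param matrix An [expression_matrix()] with >= 30 genes.
#' @param powers Candidate integer powers (default 1..20).
#' @param r2_cut Signed r2 threshold (default 0.8).
#' @param n_bins Bins for [scale_free_fit()].
#' @return List: `beta` (selected power), `fits` (data frame power, r2,
#'   slope, mean_k), `reached_cut` (logical).
#' @export
pick_soft_threshold <- function(matrix, powers = 1:20, r2_cut = 0.8,
                                n_bins = 10) {
  if (nrow(matrix$values) < 30) stop("need at least 30 genes")
  cc <- stats::cor(t(matrix$values))
  rows <- lapply(powers, function(p) {
    a <- signed_adjacency(cc, p)
    k <- connectivity(a)
    f <- tryCatch(scale_free_fit(k, n_bins = n_bins),
                  error = function(e) NULL)
    if (is.null(f)) data.frame(power = p, r2 = NA_real_, slope = NA_real_,
                               mean_k = mean(k))
    else data.frame(power = p, r2 = f$r2, slope = f$slope, mean_k = f$mean_k)
  })
  fits <- do.call(rbind, rows)
  ok <- which(!is.na(fits$r2) & fits$r2 >= r2_cut)
  if (length(ok)) {
    list(beta = fits$power[ok[1]], fits = fits, reached_cut = TRUE)
  } else {
    best <- which.max(fits$r2)
    warning("no power reached r2_cut = ", r2_cut,
            "; returning the best-fitting power")
    list(beta = fits$power[best], fits = fits, reached_cut = FALSE)
  }
}

#' Build a signed co-expression network for one region
#'
#' Computes Pearson correlations between genes, the signed adjacency at
#' power `beta`, the topological overlap matrix, and whole-network
#' connectivity.
#'
#' @param matrix An [expression_matrix()] (values already preprocessed).
#' @param beta Soft power (default 12).
#' @param tom Compute the TOM (default TRUE; skip when only adjacency-level
#'   quantities are needed, e.g. for preservation statistics).
#' @return A `coexpression_network` list: `gene_ids`, `beta`, `cor`,
#'   `adjacency`, `tom` (or `NULL`), `connectivity_k`.
#' @export
build_network <- function(matrix, beta = 12, tom = TRUE) {
  cc <- stats::cor(t(matrix$values))
  a <- signed_adjacency(cc, beta)
  structure(list(gene_ids = gene_ids(matrix),
                 beta = beta,
                 cor = cc,
                 adjacency = a,
                 tom = if (tom) topological_overlap(a) else NULL,
                 connectivity_k = connectivity(a)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %d, mean k = %.2f\n",
              length(x$gene_ids), x$beta, mean(x$connectivity_k)))
  invisible(x)
}
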