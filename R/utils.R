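#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects.
#' 1 means identical partitions, 0 is the expected value for independent
#' labelings.
#'
#' @param a,b Vectors of cluster labels (any atomic type), same length.
#' @return Numeric scalar in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(0)
  (sij - expected) / (max_index - expected)
}

# strictly upper-triangular values of a square matrix
upper_vals <- function(m) m[upper.tri(m)]

# check a square matrix is symmetric within tol
assert_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric (tolerance ", tol, ")")
  invisible(TRUE)
}

# reserved label for genes outside any module
UNASSIGNED <- "unassigned"
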