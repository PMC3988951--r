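#' Expression matrix with region tag and sample metadata
#'
#' Lightweight container for a genes x samples matrix of log2 expression
#' values, the brain region (or dataset) it came from, and per-sample
#' covariates. Gene ids are rownames, sample ids are colnames; both must be
#' unique and all values finite.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param region Single character label for the dataset/region.
#' @param metadata Data frame of per-sample covariates with a `sample_id`
#'   column matching `colnames(values)` (order-free). If `NULL`, a minimal
#'   frame holding only the sample ids is created.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `region`, `metadata` (metadata rows aligned to the column order).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, region = "HIPP")
#' dim(em$values)
#' @export
expression_matrix <- function(values, region = "unknown", metadata = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("gene ids required as rownames(values)")
  if (is.null(colnames(values))) stop("sample ids required as colnames(values)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!is.character(region) || length(region) != 1L)
    stop("`region` must be a single character label")
  if (is.null(metadata))
    metadata <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  if (!is.data.frame(metadata) || !"sample_id" %in% names(metadata))
    stop("`metadata` must be a data frame with a `sample_id` column")
  if (!setequal(metadata$sample_id, colnames(values)) ||
      nrow(metadata) != ncol(values))
    stop("metadata sample ids do not match the expression columns")
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, region = region, metadata = metadata),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, region '%s'\n",
              nrow(x$values), ncol(x$values), x$region))
  cat("metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

# subset an expr_matrix by gene and/or sample ids, keeping metadata aligned
subset_expr <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, region = x$region,
                    metadata = x$metadata[x$metadata$sample_id %in% colnames(v), ,
                                          drop = FALSE])
}
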