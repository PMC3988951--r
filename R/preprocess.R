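#' Winsorized mean
#'
#' Values below the lower empirical quantile are replaced by that quantile,
#' values above the upper quantile by that quantile, and the arithmetic mean
#' of the clipped vector is returned. Used to summarise transcript-level
#' expression robustly (default clipping below 10% and above 90%).
#'
#' Quantiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`).
#'
#' @param values Numeric vector, length >= 1, no NAs.
#' @param lower_q,upper_q Clipping quantiles, `0 <= lower_q < upper_q <= 1`.
#' @return The Winsorized mean (numeric scalar).
#' @examples
#' winsorized_mean(c(1, 2, 3, 4, 100))      # the outlier is clipped
#' @export
winsorized_mean <- function(values, lower_q = 0.10, upper_q = 0.90) {
  if (length(values) < 1) stop("empty vector")
  if (anyNA(values)) stop("values must not contain NA")
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1))
    stop("require 0 <= lower_q < upper_q <= 1")
  q <- stats::quantile(values, c(lower_q, upper_q), names = FALSE, type = 7)
  mean(pmin(pmax(values, q[1]), q[2]))
}

#' Transcript/gene filtering criteria
#'
#' A gene is retained when it (1) is detected above background (p below
#' `detection_p`, supplied as precomputed flags) in at least
#' `detection_fraction` of samples in at least one region, (2) has a
#' coefficient of variation above `cv_min` on the linear (anti-logged)
#' scale in at least one region, and (3) reaches log2 expression of at
#' least `expr_min` in at least one sample of at least one region.
#'
#' @param detection_fraction Fraction of samples that must be detected.
#' @param detection_p Nominal detection p-value threshold the flags encode
#'   (metadata only; the flags are consumed as given).
#' @param cv_min Minimum linear-scale coefficient of variation.
#' @param expr_min Minimum log2 expression reached by at least one sample.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(detection_fraction = 0.5, detection_p = 0.001,
                            cv_min = 0.05, expr_min = 5) {
  stopifnot(detection_fraction >= 0, detection_fraction <= 1,
            detection_p > 0, detection_p < 1, cv_min >= 0)
  structure(list(detection_fraction = detection_fraction,
                 detection_p = detection_p,
                 cv_min = cv_min, expr_min = expr_min),
            class = "filter_criteria")
}

#' Filter genes across regional expression matrices
#'
#' @param matrices List of [expression_matrix()] objects sharing a gene
#'   universe (identical rownames, same order).
#' @param detected Optional list of logical gene x sample matrices aligned
#'   with `matrices` (TRUE = detected above background). If `NULL`, the
#'   detection criterion is skipped (all genes treated as detected).
#' @param criteria A [filter_criteria()].
#' @return A list: `matrices` (filtered), `report` (a data frame with one row
#'   per criterion giving how many genes failed it, plus totals). The kept
#'   genes are those failing no criterion.
#' @export
filter_transcripts <- function(matrices, detected = NULL,
                               criteria = filter_criteria()) {
  stopifnot(length(matrices) >= 1)
  genes <- gene_ids(matrices[[1]])
  for (m in matrices)
    if (!identical(gene_ids(m), genes))
      stop("matrices must share an identical gene universe")
  if (!is.null(detected)) {
    if (length(detected) != length(matrices)) stop("detection flags misaligned")
    for (i in seq_along(detected)) {
      d <- detected[[i]]
      if (!is.logical(d) || !identical(dim(d), dim(matrices[[i]]$values)))
        stop("detection flags misaligned with matrix ", i)
    }
  }

  pass_detect <- if (is.null(detected)) rep(TRUE, length(genes)) else {
    Reduce(`|`, lapply(detected, function(d)
      rowMeans(d) >= criteria$detection_fraction))
  }
  # CV on the linear scale, per region, pass if any region exceeds cv_min
  pass_cv <- Reduce(`|`, lapply(matrices, function(m) {
    lin <- 2^m$values
    apply(lin, 1, stats::sd) / rowMeans(lin) > criteria$cv_min
  }))
  pass_expr <- Reduce(`|`, lapply(matrices, function(m)
    apply(m$values, 1, max) >= criteria$expr_min))

  keep <- pass_detect & pass_cv & pass_expr
  report <- data.frame(
    criterion = c("detection", "cv", "expression", "kept", "total"),
    n = c(sum(!pass_detect), sum(!pass_cv), sum(!pass_expr),
          sum(keep), length(genes)))
  out <- lapply(matrices, function(m) subset_expr(m, genes = genes[keep]))
  list(matrices = out, report = report)
}

#' Remove covariate effects from expression values
#'
#' Each gene's profile is replaced by the residuals of an ordinary
#' least-squares fit on the covariate design (categorical covariates are
#' indicator-coded), with the gene's original mean added back so expression
#' stays on its native scale. Idempotent: residualizing twice changes
#' nothing.
#'
#' @param matrix An [expression_matrix()].
#' @param covariate_names Character vector of columns of `matrix$metadata`.
#' @return A new [expression_matrix()] of residualized values.
#' @export
residualize <- function(matrix, covariate_names) {
  md <- matrix$metadata
  missing <- setdiff(covariate_names, names(md))
  if (length(missing)) stop("covariates not in metadata: ",
                            paste(missing, collapse = ", "))
  df <- md[covariate_names]
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  X <- stats::model.matrix(~ ., data = df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, t(matrix$values))
  res <- t(fit$residuals) + rowMeans(matrix$values)
  dimnames(res) <- dimnames(matrix$values)
  expression_matrix(res, region = matrix$region, metadata = md)
}

#' Flag outlier samples by inter-array correlation
#'
#' Computes each sample's mean Pearson correlation with all other samples
#' (IAC); samples strictly below `mean(IAC) - sd_threshold * sd(IAC)` are
#' removed, and the procedure repeats on the reduced set until no sample is
#' flagged.
#'
#' @param matrix An [expression_matrix()] with >= 3 samples.
#' @param sd_threshold Number of SDs below the mean IAC (default 3); the
#'   boundary itself is NOT flagged (strict inequality).
#' @return Character vector of flagged sample ids (possibly empty), in the
#'   order they were removed.
#' @export
detect_outlier_samples <- function(matrix, sd_threshold = 3) {
  vals <- matrix$values
  if (ncol(vals) < 3) stop("need at least 3 samples")
  flagged <- character()
  repeat {
    if (ncol(vals) < 3) break
    cc <- stats::cor(vals)
    iac <- (colSums(cc) - 1) / (ncol(vals) - 1)
    cut <- mean(iac) - sd_threshold * stats::sd(iac)
    bad <- names(iac)[iac < cut]
    if (!length(bad)) break
    flagged <- c(flagged, bad)
    vals <- vals[, setdiff(colnames(vals), bad), drop = FALSE]
  }
  flagged
}
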