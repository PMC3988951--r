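#' Regional expression contrast for one gene (paired t test)
#'
#' Pairs samples by individual id across two regions, applies a classical
#' paired t test to the log2 values, and reports the fold change
#' `2^(mean log2 difference)` (region A over region B).
#'
#' @param matrices List of [expression_matrix()] objects; metadata must
#'   contain `individual`.
#' @param gene Gene id present in both regions.
#' @param region_a,region_b Region labels matching `$region`.
#' @return List: `gene`, `region_a`, `region_b`, `n_pairs`,
#'   `mean_log2_diff`, `fold_change`, `t_statistic`, `p_value`.
#' @export
region_contrast <- function(matrices, gene, region_a, region_b) {
  regs <- vapply(matrices, function(m) m$region, character(1))
  ia <- match(region_a, regs); ib <- match(region_b, regs)
  if (is.na(ia) || is.na(ib)) stop("region not found")
  ma <- matrices[[ia]]; mb <- matrices[[ib]]
  if (!"individual" %in% names(ma$metadata))
    stop("metadata must contain an `individual` column")
  shared <- intersect(ma$metadata$individual, mb$metadata$individual)
  if (length(shared) < 3) stop("fewer than 3 paired individuals")
  sa <- ma$metadata$sample_id[match(shared, ma$metadata$individual)]
  sb <- mb$metadata$sample_id[match(shared, mb$metadata$individual)]
  d <- ma$values[gene, sa] - mb$values[gene, sb]
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s < 1e-10 * max(abs(m), 1)) {
    if (abs(m) < 1e-12) {
      t_stat <- 0; p <- 1
    } else {
      stop("degenerate paired differences: zero variance with non-zero mean")
    }
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  list(gene = gene, region_a = region_a, region_b = region_b,
       n_pairs = n, mean_log2_diff = m, fold_change = 2^m,
       t_statistic = t_stat, p_value = p)
}

#' Covariate association of one gene's expression
#'
#' Ordinary least-squares regression of a gene's log2 expression on a
#' covariate of interest (e.g. age or sex), adjusting for further
#' covariates; returns the covariate's effect (slope for numeric, group
#' difference for a 2-level factor) and its t-test p-value.
#'
#' @param matrix An [expression_matrix()] with >= 10 samples.
#' @param gene Gene id.
#' @param covariate Name of the metadata column of interest.
#' @param adjust Character vector of adjuster columns (may be empty).
#' @return List: `effect`, `p_value`, `term`.
#' @export
covariate_association <- function(matrix, gene, covariate,
                                  adjust = character()) {
  md <- matrix$metadata
  if (ncol(matrix$values) < 10) stop("need at least 10 samples")
  vars <- c(covariate, adjust)
  missing <- setdiff(vars, names(md))
  if (length(missing)) stop("covariates not in metadata: ",
                            paste(missing, collapse = ", "))
  df <- md[vars]
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  df$.y <- matrix$values[gene, ]
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("collinear adjusters: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)$coefficients
  hit <- grep(paste0("^", covariate), rownames(sm))
  if (!length(hit)) stop("covariate term absent from the fit")
  list(effect = unname(sm[hit[1], "Estimate"]),
       p_value = unname(sm[hit[1], "Pr(>|t|)"]),
       term = rownames(sm)[hit[1]])
}
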