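#' Read an expression TSV
#'
#' Tab-separated table, first column gene id, header line of sample ids,
#' numeric cells (log2 expression).
#'
#' @param path File path.
#' @param region Region label to attach.
#' @param metadata Optional metadata data frame (see [expression_matrix()]);
#'   rows are matched to the file's samples by `sample_id`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, region = "unknown", metadata = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression table needs >= 1 sample column")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d (gene %s), column %s",
                 bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(vals))
  if (!is.null(metadata))
    metadata <- metadata[metadata$sample_id %in% colnames(num), , drop = FALSE]
  expression_matrix(num, region = region, metadata = metadata)
}

#' Write an expression TSV
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = gene_ids(matrix), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read detection flags (TRUE = detected above background)
#'
#' Same layout as an expression TSV with logical/0-1 cells.
#'
#' @param path File path.
#' @return Logical gene x sample matrix.
#' @export
read_detection_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene id in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "logical"
  rownames(m) <- ids
  m
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' Duplicate genes within a set are dropped with a warning.
#'
#' @param path File path.
#' @return List of [gene_set()] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    sets[[length(sets) + 1L]] <-
      gene_set(parts[1], parts[-(1:2)], source = parts[2])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$source)) s$source else "na", s$genes),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' @param path File path (columns include `sample_id`).
#' @return Data frame.
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have a sample_id column")
  md
}
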