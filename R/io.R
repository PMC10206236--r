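# Plain-text readers and writers for the pipeline's tabular interchange
# formats (TSV matrices, BED-like peak tables, chromosome-size tables).

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header
#' @param path Input path.
#' @param ... Passed to [utils::read.delim()].
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write a numeric matrix as TSV (first column = feature names)
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id Name of the feature-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id = "feature") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id
  write_tsv(df, path)
}

#' Read a numeric matrix from TSV (first column = feature names)
#' @param path Input path.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write peaks as a BED-like table
#'
#' Columns chrom, start, end, name, score-like value, plus any remaining
#' columns; no header (BED dialect).
#' @param peaks Peak data frame.
#' @param path Output path.
#' @param score_col Which column to place in the BED score slot.
#' @export
write_bed <- function(peaks, path, score_col = "score") {
  nm <- peaks$name %||% sprintf("peak_%05d", seq_len(nrow(peaks)))
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, nm,
                   peaks[[score_col]] %||% 0)
  extra <- setdiff(names(peaks),
                   c("chrom", "start", "end", "name", score_col))
  for (e in extra) df[[e]] <- peaks[[e]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like table
#' @param path Input path.
#' @param col_names Column names to assign (by position; extra file columns
#'   are kept with default names).
#' @export
read_bed <- function(path,
                     col_names = c("chrom", "start", "end", "name",
                                   "score")) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  n <- min(length(col_names), ncol(df))
  names(df)[seq_len(n)] <- col_names[seq_len(n)]
  df
}

#' Read a chromosome-size table as a toy genome
#' @param path Two-column TSV (chrom, size), no header.
#' @export
read_genome_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  toy_genome(stats::setNames(as.numeric(df[[2]]), df[[1]]))
}
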