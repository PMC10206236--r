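# Count matrix container: features (peaks or genes) x samples, with
# per-sample library sizes (column sums of the raw counts) and
# normalization factors.

#' Construct a count matrix
#'
#' @param counts Nonnegative numeric matrix, features in rows, samples in
#'   columns.
#' @return Object of class `count_matrix`: list with `counts`, `lib_sizes`
#'   (column sums), and `norm_factors` (initialized to 1).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%d", seq_len(ncol(counts)))
  }
  structure(list(
    counts = counts,
    lib_sizes = colSums(counts),
    norm_factors = stats::setNames(rep(1, ncol(counts)), colnames(counts))
  ), class = "count_matrix")
}

# Accept either a raw matrix or a count_matrix everywhere downstream.
as_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  library sizes:",
      paste(format(x$lib_sizes, big.mark = ","), collapse = " "), "\n")
  invisible(x)
}
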