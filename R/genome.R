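# Toy genome: a named vector of chromosome lengths. All genomic intervals
# in this package are 0-based half-open (BED dialect); summits are 0-based
# single positions.

#' Construct a toy genome
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#'   The default includes two autosome-like chromosomes and `chrY`, whose
#'   peaks the consensus builder removes.
#' @return Object of class `toy_genome` (named numeric vector).
#' @export
toy_genome <- function(chrom_sizes = c(chr1 = 1e6, chr2 = 5e5, chrY = 2e5)) {
  if (length(chrom_sizes) == 0) stop("empty genome")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))) ||
      anyDuplicated(names(chrom_sizes))) {
    stop("chrom_sizes must have unique non-empty names")
  }
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  structure(as.numeric(chrom_sizes),
            names = names(chrom_sizes), class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("Toy genome:", length(x), "chromosomes,",
      format(sum(x), big.mark = ","), "bp total\n")
  for (ch in names(x)) cat(sprintf("  %-6s %s bp\n", ch,
                                   format(x[[ch]], big.mark = ",")))
  invisible(x)
}
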