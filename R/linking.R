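# Regulatory-domain construction (basal-plus-extension, the convention of
# region-to-gene association tools), peak -> gene association by midpoint
# containment, and the intersection logic that calls knockdown-
# downregulated enhancer-gene pairs.

#' Basal-plus-extension regulatory domains
#'
#' Each gene gets a basal domain of `upstream` bp upstream and `downstream`
#' bp downstream of its TSS (strand-aware; defaults 5 kb / 1 kb), then each
#' side is extended to the nearest neighboring gene's basal-domain boundary
#' or by at most `max_extension` bp (default 1 Mb), whichever is closer,
#' clipped to the chromosome. Coordinates are 0-based half-open: a + strand
#' basal domain is `[tss - upstream, tss + downstream)` and a - strand one
#' is its mirror `[tss - downstream + 1, tss + upstream + 1)`.
#'
#' @param tss Data frame `gene`, `chrom`, `tss`, `strand` (from
#'   [simulate_gene_models()] or a GTF-derived table).
#' @param genome A [toy_genome()] (or named chromosome-length vector).
#' @param upstream,downstream Basal extents, bp.
#' @param max_extension Maximum extension per side, bp.
#' @return Data frame `gene`, `chrom`, `strand`, `tss`, `basal_start`,
#'   `basal_end`, `ext_start`, `ext_end` (basal always inside extended).
#' @export
basal_regulatory_domains <- function(tss, genome, upstream = 5000,
                                     downstream = 1000,
                                     max_extension = 1e6) {
  req <- c("gene", "chrom", "tss", "strand")
  if (!all(req %in% names(tss))) {
    stop("tss needs columns gene, chrom, tss, strand")
  }
  if (any(!tss$strand %in% c("+", "-"))) stop("strand must be + or -")
  len <- as.numeric(genome[tss$chrom])
  if (anyNA(len)) stop("unknown chromosome in tss table")
  if (any(tss$tss < 0 | tss$tss >= len)) stop("TSS outside genome")

  plus <- tss$strand == "+"
  bs <- ifelse(plus, tss$tss - upstream, tss$tss - downstream + 1)
  be <- ifelse(plus, tss$tss + downstream, tss$tss + upstream + 1)
  bs <- pmax(bs, 0)
  be <- pmin(be, len)

  n <- nrow(tss)
  es <- numeric(n)
  ee <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(tss$chrom == tss$chrom[i]), i)
    left <- be[same][be[same] <= bs[i]]
    es[i] <- min(bs[i], max(bs[i] - max_extension, 0, left))
    right <- bs[same][bs[same] >= be[i]]
    ee[i] <- max(be[i], min(be[i] + max_extension, len[i], right))
  }
  out <- data.frame(
    gene = tss$gene, chrom = tss$chrom, strand = tss$strand, tss = tss$tss,
    basal_start = bs, basal_end = be, ext_start = es, ext_end = ee,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Associate peaks with genes through regulatory domains
#'
#' A peak is associated with every gene whose extended regulatory domain
#' contains the peak's midpoint (`start + width %/% 2`); a peak may hit
#' zero, one, or several genes. `rule = "overlap"` instead requires any
#' overlap between the peak interval and the extended domain.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, and a `name`
#'   column; row indices are used if `name` is absent).
#' @param domains Output of [basal_regulatory_domains()].
#' @param rule `"midpoint"` (default) or `"overlap"`.
#' @return Data frame of association edges `peak`, `gene`, sorted by
#'   (peak, gene).
#' @export
associate_peaks_genes <- function(peaks, domains,
                                  rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  pk <- if ("name" %in% names(peaks)) {
    as.character(peaks$name)
  } else {
    sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  if (nrow(peaks) == 0 || nrow(domains) == 0) {
    return(data.frame(peak = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  }
  q <- if (rule == "midpoint") {
    mid <- peaks$start + (peaks$end - peaks$start) %/% 2
    data.frame(chrom = peaks$chrom, start = mid, end = mid + 1)
  } else {
    data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end)
  }
  dm <- data.frame(chrom = domains$chrom, start = domains$ext_start,
                   end = domains$ext_end)
  ov <- overlap_pairs(q, dm)
  out <- data.frame(peak = pk[ov$q], gene = as.character(domains$gene[ov$s]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$peak, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_contrast_sets <- function(x, what) {
  if (!is.list(x)) x <- list(x)
  x <- lapply(x, as.character)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- sprintf("%s_contrast%d", what, seq_along(x))
  }
  x
}

#' Call knockdown-downregulated enhancer-gene pairs
#'
#' A pair (peak, gene) is reported iff the association edge exists, the
#' gene is downregulated under `gene_rule` across the gene contrasts
#' (`"either"`, the default, requires at least one contrast; `"both"`
#' requires all), and the peak is downregulated under `peak_rule` across
#' the peak contrasts. Evidence columns record which contrasts supported
#' each side. Enlarging any input set never removes a pair.
#'
#' @param edges Association edges from [associate_peaks_genes()].
#' @param down_genes Character vector or (optionally named) list of per-
#'   contrast downregulated gene sets.
#' @param down_peaks Character vector or list of per-contrast downregulated
#'   peak sets.
#' @param gene_rule,peak_rule `"either"` (default) or `"both"`.
#' @return Data frame `peak`, `gene`, `gene_contrasts`, `peak_contrasts`,
#'   sorted by (gene, peak).
#' @export
enhancer_gene_pairs <- function(edges, down_genes, down_peaks,
                                gene_rule = c("either", "both"),
                                peak_rule = c("either", "both")) {
  gene_rule <- match.arg(gene_rule)
  peak_rule <- match.arg(peak_rule)
  dg <- normalize_contrast_sets(down_genes, "gene")
  dp <- normalize_contrast_sets(down_peaks, "peak")
  combine <- function(sets, rule) {
    if (rule == "either") Reduce(union, sets) else Reduce(intersect, sets)
  }
  genes_ok <- combine(dg, gene_rule)
  peaks_ok <- combine(dp, peak_rule)
  hit <- edges$gene %in% genes_ok & edges$peak %in% peaks_ok
  out <- edges[hit, c("peak", "gene"), drop = FALSE]
  if (nrow(out) > 0) {
    out$gene_contrasts <- vapply(out$gene, function(g) {
      paste(names(dg)[vapply(dg, function(s) g %in% s, logical(1))],
            collapse = ",")
    }, character(1))
    out$peak_contrasts <- vapply(out$peak, function(p) {
      paste(names(dp)[vapply(dp, function(s) p %in% s, logical(1))],
            collapse = ",")
    }, character(1))
  } else {
    out$gene_contrasts <- character(0)
    out$peak_contrasts <- character(0)
  }
  out <- out[order(out$gene, out$peak, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
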