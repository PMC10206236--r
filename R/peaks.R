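# Fixed-width consensus peak construction. All intervals are 0-based
# half-open; a summit at s becomes [s - flank, s + flank + 1), i.e. 501 bp
# at the default flank of 250. Overlap means >= 1 shared bp on the same
# chromosome. Interval intersection is delegated to IRanges; the test suite
# checks every operation against quadratic brute-force oracles.

to_iranges <- function(start, end) {
  # half-open [start, end) -> 1-based closed IRanges
  IRanges::IRanges(start = start + 1, end = end)
}

# All (i, j) row-index pairs with >= 1 bp overlap between df1 and df2.
overlap_pairs <- function(df1, df2) {
  res_q <- integer(0)
  res_s <- integer(0)
  for (ch in intersect(unique(df1$chrom), unique(df2$chrom))) {
    i1 <- which(df1$chrom == ch)
    i2 <- which(df2$chrom == ch)
    h <- IRanges::findOverlaps(
      to_iranges(df1$start[i1], df1$end[i1]),
      to_iranges(df2$start[i2], df2$end[i2])
    )
    res_q <- c(res_q, i1[S4Vectors::queryHits(h)])
    res_s <- c(res_s, i2[S4Vectors::subjectHits(h)])
  }
  data.frame(q = res_q, s = res_s)
}

#' Standardize summit calls to fixed-width peaks
#'
#' Extends each summit by `flank` bp on both sides to a fixed width of
#' `2 * flank + 1` bp (501 at the default). Peaks that would run past either
#' chromosome end are dropped, not trimmed, preserving the fixed-width
#' invariant that downstream normalization assumes.
#'
#' @param summits Data frame with columns `chrom`, `summit` (0-based
#'   position), `score` (positive caller significance score).
#' @param genome A [toy_genome()] (or named vector of chromosome lengths).
#' @param flank Extension on each side, bp (default 250).
#' @return Data frame `chrom`, `start`, `end`, `summit`, `score`, `name`.
#' @export
standardize_peaks <- function(summits, genome, flank = 250L) {
  req <- c("chrom", "summit", "score")
  if (!all(req %in% names(summits))) {
    stop("summits needs columns chrom, summit, score")
  }
  bad <- !summits$chrom %in% names(genome)
  if (any(bad)) {
    stop("unknown chromosome: ", paste(unique(summits$chrom[bad]),
                                       collapse = ", "))
  }
  start <- summits$summit - flank
  end <- summits$summit + flank + 1
  keep <- start >= 0 & end <= as.numeric(genome[summits$chrom])
  out <- data.frame(
    chrom = summits$chrom[keep],
    start = start[keep],
    end = end[keep],
    summit = summits$summit[keep],
    score = summits$score[keep],
    stringsAsFactors = FALSE
  )
  out$name <- sprintf("%s_%d", out$chrom, out$summit)
  rownames(out) <- NULL
  out
}

#' Remove peaks overlapping a blacklist
#'
#' Drops any peak sharing at least one bp with any blacklist interval.
#' Half-open semantics: a peak whose `end` equals a blacklist `start` merely
#' abuts it and is kept.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, ...).
#' @param blacklist Data frame `chrom`, `start`, `end`; may be empty.
#' @return The surviving peaks, order preserved.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    return(peaks)
  }
  ov <- overlap_pairs(peaks, blacklist)
  if (nrow(ov) == 0) {
    return(peaks)
  }
  out <- peaks[-unique(ov$q), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score-per-million normalization of one sample's peaks
#'
#' `spm_i = score_i / (sum(score) / 1e6)`, so a sample's spm values sum to
#' one million and are invariant to any positive rescaling of its scores.
#'
#' @param peaks One sample's peak data frame with a positive `score` column.
#' @return The peaks with an added `spm` column.
#' @export
score_per_million <- function(peaks) {
  if (!"score" %in% names(peaks)) stop("peaks need a score column")
  if (nrow(peaks) == 0) stop("zero total score")
  if (any(peaks$score <= 0)) stop("all scores must be positive")
  tot <- sum(peaks$score)
  if (tot <= 0) stop("zero total score")
  peaks$spm <- peaks$score / (tot / 1e6)
  peaks
}

#' Iterative overlap removal
#'
#' Greedy canonical reduction: repeatedly keep the highest-ranked remaining
#' peak and discard every remaining peak overlapping it (>= 1 bp, same
#' chromosome) until none remain. Rank ties are broken by (chrom, start,
#' end) lexicographically, which together with the rank makes the output
#' independent of input order.
#'
#' @param peaks Peak data frame.
#' @param rank_key `"score"` (within-sample reduction) or `"spm"`
#'   (cross-sample reduction).
#' @return The kept peaks, sorted by coordinate; mutually non-overlapping.
#' @export
iterative_overlap_reduce <- function(peaks, rank_key = c("score", "spm")) {
  rank_key <- match.arg(rank_key)
  if (!rank_key %in% names(peaks)) {
    stop("peaks lack the rank column '", rank_key, "'")
  }
  n <- nrow(peaks)
  if (n <= 1) {
    return(peaks)
  }
  key <- peaks[[rank_key]]
  ord <- order(-key, peaks$chrom, peaks$start, peaks$end, method = "radix")
  ov <- overlap_pairs(peaks, peaks)
  ov <- ov[ov$q != ov$s, , drop = FALSE]
  nb <- split(ov$s, factor(ov$q, levels = seq_len(n)))
  discarded <- rep(FALSE, n)
  kept <- rep(FALSE, n)
  for (i in ord) {
    if (discarded[i]) next
    kept[i] <- TRUE
    discarded[nb[[i]]] <- TRUE
  }
  out <- peaks[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the reproducible consensus peak set
#'
#' Pools per-sample peak sets (each already standardized, blacklist
#' filtered, within-sample reduced, and spm-normalized), applies the
#' cross-sample iterative overlap removal ranked by spm, counts per retained
#' peak the number of distinct samples contributing at least one overlapping
#' original peak (the retained peak's own sample counts), and keeps peaks
#' with `spm >= spm_min` and `support >= min_samples`. Peaks on chrY are
#' removed. By default the spm threshold is applied after pooling, on each
#' retained peak's own spm (`spm_filter = "pre"` instead filters each sample
#' before pooling); spm is never recomputed after pooling.
#'
#' @param sample_peaks Named list of per-sample peak data frames, each with
#'   an `spm` column (see [score_per_million()]).
#' @param spm_min Minimum score-per-million (default 5).
#' @param min_samples Minimum supporting samples (default 2).
#' @param spm_filter `"post"` (default) or `"pre"`.
#' @param drop_chrY Remove chrY peaks (default TRUE).
#' @return Consensus peak data frame (`chrom`, `start`, `end`, `summit`,
#'   `score`, `spm`, `sample`, `support`, `name`), coordinate-sorted,
#'   pairwise disjoint.
#' @export
build_reproducible_set <- function(sample_peaks, spm_min = 5,
                                   min_samples = 2L,
                                   spm_filter = c("post", "pre"),
                                   drop_chrY = TRUE) {
  spm_filter <- match.arg(spm_filter)
  if (length(sample_peaks) < 1) stop("need at least one sample peak set")
  if (is.null(names(sample_peaks))) {
    names(sample_peaks) <- sprintf("sample%d", seq_along(sample_peaks))
  }
  for (df in sample_peaks) {
    if (nrow(df) > 0 && !"spm" %in% names(df)) {
      stop("every sample must be spm-normalized (run score_per_million)")
    }
  }
  if (spm_filter == "pre") {
    sample_peaks <- lapply(sample_peaks, function(df) {
      df[df$spm >= spm_min, , drop = FALSE]
    })
  }
  pooled <- do.call(rbind, Map(function(df, nm) {
    if (nrow(df) == 0) return(NULL)
    df$sample <- nm
    df
  }, sample_peaks, names(sample_peaks)))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), summit = numeric(0),
                      score = numeric(0), spm = numeric(0),
                      sample = character(0), support = integer(0),
                      name = character(0), stringsAsFactors = FALSE)
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(empty)
  }
  rownames(pooled) <- NULL
  reduced <- iterative_overlap_reduce(pooled, rank_key = "spm")
  ov <- overlap_pairs(reduced, pooled)
  supp <- tapply(pooled$sample[ov$s],
                 factor(ov$q, levels = seq_len(nrow(reduced))),
                 function(s) length(unique(s)))
  reduced$support <- as.integer(ifelse(is.na(supp), 0L, supp))

  keep <- reduced$support >= min_samples
  if (spm_filter == "post") keep <- keep & reduced$spm >= spm_min
  if (drop_chrY) keep <- keep & reduced$chrom != "chrY"
  out <- reduced[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    return(empty)
  }
  out <- out[order(out$chrom, out$start, out$end, method = "radix"), ,
             drop = FALSE]
  out$name <- sprintf("consensus_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  # hard invariant: a finalized set is pairwise disjoint
  self <- overlap_pairs(out, out)
  if (any(self$q != self$s)) stop("internal error: consensus set overlaps")
  out
}

#' Count fragments per consensus peak
#'
#' Cell (i, j) is the number of sample-j fragments overlapping peak i by at
#' least one bp. A fragment spanning two disjoint consensus peaks increments
#' both.
#'
#' @param fragments Named list of per-sample fragment data frames
#'   (`chrom`, `start`, `end`).
#' @param peakset Consensus peak data frame (see
#'   [build_reproducible_set()]).
#' @return A [count_matrix()] (peaks x samples).
#' @export
count_fragments <- function(fragments, peakset) {
  if (!is.list(fragments) || is.data.frame(fragments)) {
    fragments <- list(sample1 = fragments)
  }
  if (is.null(names(fragments))) {
    names(fragments) <- sprintf("sample%d", seq_along(fragments))
  }
  counts <- vapply(fragments, function(fr) {
    if (nrow(fr) == 0) return(integer(nrow(peakset)))
    ov <- overlap_pairs(peakset, fr)
    tabulate(ov$q, nbins = nrow(peakset))
  }, integer(nrow(peakset)))
  counts <- matrix(counts, nrow = nrow(peakset),
                   dimnames = list(peakset$name, names(fragments)))
  count_matrix(counts)
}
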