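# Bias-corrected motif accessibility deviations over the consensus peak
# set: per-(motif, sample) raw deviations of observed fragment counts from
# their sample-depth expectation, standardized against GC- and
# accessibility-matched background peak sets, plus the condition contrast
# of the resulting z-scores ("motif scores").

#' Per-peak GC fraction
#'
#' Computes the fraction of G/C bases in each peak window from chromosome
#' sequences, or validates and returns a precomputed per-peak table.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, optionally
#'   `name`).
#' @param sequences Named character vector (or list) of chromosome
#'   sequences.
#' @param gc Optional precomputed per-peak GC fractions (skips
#'   `sequences`).
#' @return Numeric vector in `[0, 1]`, one value per peak, named by peak
#'   name when available.
#' @export
compute_gc <- function(peaks, sequences = NULL, gc = NULL) {
  nm <- if ("name" %in% names(peaks)) peaks$name else NULL
  if (!is.null(gc)) {
    if (!is.null(names(gc)) && !is.null(nm)) {
      gc <- gc[nm]
    }
    if (length(gc) != nrow(peaks) || anyNA(gc)) {
      stop("gc table does not cover every peak")
    }
    if (any(gc < 0 | gc > 1)) stop("gc fractions must lie in [0, 1]")
    return(stats::setNames(as.numeric(gc), nm))
  }
  if (is.null(sequences)) stop("provide sequences or a gc table")
  sequences <- as.list(sequences)
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]
    s <- sequences[[ch]]
    if (is.null(s)) stop("missing sequence for chromosome ", ch)
    if (peaks$end[i] > nchar(s)) stop("peak extends past sequence end")
    win <- toupper(substr(s, peaks$start[i] + 1, peaks$end[i]))
    chars <- strsplit(win, "", fixed = TRUE)[[1]]
    mean(chars %in% c("G", "C"))
  }, numeric(1))
  stats::setNames(out, nm)
}

#' Sample GC/accessibility-matched background peaks
#'
#' Standardizes the two covariates (GC fraction and mean accessibility,
#' conventionally per-peak mean log-CPM) to unit variance, finds each
#' peak's `n_neighbors` nearest peaks in that 2-D space (self excluded),
#' and draws `n_bg_sets` background peaks per foreground peak uniformly
#' with replacement from its neighbor set. Covariates with zero variance
#' are dropped with a warning; if both are degenerate, sampling is uniform
#' over all other peaks.
#'
#' @param gc Per-peak GC fraction.
#' @param accessibility Per-peak mean accessibility (e.g. mean log-CPM
#'   across samples).
#' @param n_bg_sets Number of background sets (default 50).
#' @param n_neighbors Neighborhood size (default 50; needs
#'   `length(gc) >= n_neighbors + 1`).
#' @param seed Optional seed.
#' @return Integer matrix, peaks x `n_bg_sets`, of background peak indices.
#' @export
sample_background_peaks <- function(gc, accessibility, n_bg_sets = 50L,
                                    n_neighbors = 50L, seed = NULL) {
  n <- length(gc)
  if (length(accessibility) != n) stop("covariate lengths differ")
  if (n < n_neighbors + 1) stop("need at least n_neighbors + 1 peaks")
  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) NULL else (v - mean(v)) / s
  }
  cov_list <- Filter(Negate(is.null), list(std(gc), std(accessibility)))
  if (length(cov_list) < 2) {
    warning("degenerate covariate(s); background matching weakened")
  }
  with_seed(seed, {
    bg <- matrix(0L, n, n_bg_sets)
    if (length(cov_list) == 0) {
      for (i in seq_len(n)) {
        bg[i, ] <- sample(seq_len(n)[-i], n_bg_sets, replace = TRUE)
      }
    } else {
      X <- do.call(cbind, cov_list)
      chunk <- 512L
      for (from in seq(1L, n, by = chunk)) {
        to <- min(from + chunk - 1L, n)
        block <- X[from:to, , drop = FALSE]
        # squared Euclidean distances block x all
        d2 <- outer(rowSums(block^2), rowSums(X^2), "+") -
          2 * tcrossprod(block, X)
        for (r in seq_len(nrow(d2))) {
          i <- from + r - 1L
          d2[r, i] <- Inf # exclude self
          nbr <- order(d2[r, ])[seq_len(n_neighbors)]
          bg[i, ] <- nbr[sample.int(n_neighbors, n_bg_sets, replace = TRUE)]
        }
      }
    }
    bg
  })
}

#' Compute motif deviations and z-scores
#'
#' For motif m and sample j, the observed count is
#' `X_mj = sum of counts over motif-matching peaks`, the expected count is
#' `E_mj = T_j * (sum of matching-peak totals) / (grand total)` where `T_j`
#' is the sample depth, and the raw deviation is `(X - E) / E`. Each
#' background set substitutes the matched background peak (multiset) for
#' every motif peak and recomputes the same statistic; the z-score
#' standardizes the raw deviation by the mean and standard deviation
#' (denominator `n_bg_sets - 1`) of the background deviations. Raw
#' deviations are invariant to a global rescaling of all samples, and a
#' motif matching all peaks has raw deviation exactly 0.
#'
#' @param counts Count matrix or [count_matrix()] (peaks x samples).
#' @param motifs Binary motif x peak matrix (rows = motifs); every motif
#'   must match at least one peak.
#' @param backgrounds Background index matrix from
#'   [sample_background_peaks()].
#' @return Object of class `motif_deviation`: list with `raw_dev` and `z`
#'   (motif x sample matrices), `motifs`, `samples`.
#' @export
compute_deviations <- function(counts, motifs, backgrounds) {
  cm <- as_counts(counts)
  M <- as.matrix(motifs)
  storage.mode(M) <- "numeric"
  if (ncol(M) != nrow(cm)) {
    stop("motif matrix columns must match count matrix rows")
  }
  if (nrow(backgrounds) != nrow(cm)) {
    stop("backgrounds must have one row per peak")
  }
  if (any(rowSums(M) == 0)) stop("motif with zero matching peaks")

  t_i <- rowSums(cm)
  t_j <- colSums(cm)
  t_tot <- sum(cm)
  X <- M %*% cm
  E <- (M %*% t_i) %*% t(t_j) / t_tot
  if (any(E == 0)) stop("motif with zero expected counts")
  raw <- (X - E) / E

  n_bg <- ncol(backgrounds)
  s1 <- matrix(0, nrow(M), ncol(cm))
  s2 <- matrix(0, nrow(M), ncol(cm))
  for (b in seq_len(n_bg)) {
    idx <- backgrounds[, b]
    xb <- M %*% cm[idx, , drop = FALSE]
    eb <- (M %*% t_i[idx]) %*% t(t_j) / t_tot
    db <- (xb - eb) / eb
    s1 <- s1 + db
    s2 <- s2 + db * db
  }
  mb <- s1 / n_bg
  vb <- pmax((s2 - n_bg * mb * mb) / (n_bg - 1), 0)
  z <- (raw - mb) / sqrt(vb)
  flat <- vb == 0
  if (any(flat)) {
    z[flat] <- ifelse(raw[flat] == mb[flat], 0, NA_real_)
  }
  dn <- list(rownames(M), colnames(cm))
  dimnames(raw) <- dn
  dimnames(z) <- dn
  structure(list(
    raw_dev = raw,
    z = z,
    motifs = rownames(M),
    samples = colnames(cm)
  ), class = "motif_deviation")
}

#' Condition contrast of motif scores
#'
#' `delta_m = mean(z_mj, j in A) - mean(z_mj, j in B)`; ranking by delta
#' descending orders motifs by how much their enrichment drops from
#' condition A to condition B. Swapping the conditions negates the
#' contrast.
#'
#' @param dev A `motif_deviation` from [compute_deviations()].
#' @param cond_a,cond_b Sample names or indices of the two conditions
#'   (non-empty).
#' @return Named per-motif delta vector, ordered as `dev$motifs`.
#' @export
delta_scores <- function(dev, cond_a, cond_b) {
  if (!inherits(dev, "motif_deviation")) stop("dev must be a motif_deviation")
  idx <- function(g) {
    i <- if (is.character(g)) match(g, dev$samples) else as.integer(g)
    if (length(i) == 0) stop("empty condition")
    if (anyNA(i)) stop("unknown sample in condition")
    i
  }
  a <- idx(cond_a)
  b <- idx(cond_b)
  d <- rowMeans(dev$z[, a, drop = FALSE]) -
    rowMeans(dev$z[, b, drop = FALSE])
  stats::setNames(d, dev$motifs)
}

#' @export
print.motif_deviation <- function(x, ...) {
  cat(sprintf("Motif deviations: %d motifs x %d samples\n",
              length(x$motifs), length(x$samples)))
  invisible(x)
}
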