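# Brute-force oracles and fixture builders. Every oracle is deliberately
# quadratic / literal so it stays independent of the package's interval and
# statistics machinery.

# --- interval oracles (0-based half-open, >= 1 bp overlap) -----------------

bf_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# literal "keep top, discard overlappers, repeat" reduction
bf_iterative_reduce <- function(peaks, key) {
  kept <- list()
  pool <- peaks
  while (nrow(pool) > 0) {
    ord <- order(-pool[[key]], pool$chrom, pool$start, pool$end,
                 method = "radix")
    top <- pool[ord[1], , drop = FALSE]
    kept[[length(kept) + 1]] <- top
    ov <- pool$chrom == top$chrom & pool$start < top$end &
      pool$end > top$start
    pool <- pool[!ov, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$chrom, out$start, out$end, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

bf_count_fragments <- function(frags, peaks) {
  m <- matrix(0L, nrow(peaks), length(frags),
              dimnames = list(peaks$name, names(frags)))
  for (j in seq_along(frags)) {
    fr <- frags[[j]]
    for (i in seq_len(nrow(peaks))) {
      m[i, j] <- sum(fr$chrom == peaks$chrom[i] & fr$start < peaks$end[i] &
                       fr$end > peaks$start[i])
    }
  }
  m
}

bf_consensus <- function(sample_peaks, spm_min = 5, min_samples = 2) {
  pooled <- do.call(rbind, Map(function(df, nm) {
    if (nrow(df) == 0) return(NULL)
    df$sample <- nm
    df
  }, sample_peaks, names(sample_peaks)))
  if (is.null(pooled) || nrow(pooled) == 0) return(pooled)
  rownames(pooled) <- NULL
  red <- bf_iterative_reduce(pooled, "spm")
  supp <- integer(nrow(red))
  for (i in seq_len(nrow(red))) {
    ov <- pooled$chrom == red$chrom[i] & pooled$start < red$end[i] &
      pooled$end > red$start[i]
    supp[i] <- length(unique(pooled$sample[ov]))
  }
  red$support <- supp
  out <- red[supp >= min_samples & red$spm >= spm_min &
               red$chrom != "chrY", , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- survival oracle: literal per-event-time hypergeometric loop -----------

bf_logrank <- function(time, event, group) {
  g <- factor(group)
  k <- nlevels(g)
  lv <- levels(g)
  O <- rep(0, k)
  E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    nj <- vapply(lv, function(l) sum(time >= t & g == l), numeric(1))
    dj <- vapply(lv, function(l) sum(time == t & event == 1 & g == l),
                 numeric(1))
    n <- sum(nj)
    d <- sum(dj)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (a in 1:k) {
        for (b in 1:k) {
          V[a, b] <- V[a, b] + d * (n - d) / (n - 1) * (nj[a] / n) *
            ((a == b) - nj[b] / n)
        }
      }
    }
  }
  oe <- (O - E)[-k]
  chi2 <- drop(t(oe) %*% solve(V[-k, -k, drop = FALSE]) %*% oe)
  list(chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

# --- BH oracle: literal sorted-cummin step-up ------------------------------

bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(p[o][i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# --- regulatory-domain oracles ---------------------------------------------

bf_domains <- function(tss, genome, up = 5000, down = 1000, maxext = 1e6) {
  n <- nrow(tss)
  len <- as.numeric(genome[tss$chrom])
  bs <- be <- es <- ee <- numeric(n)
  for (i in seq_len(n)) {
    if (tss$strand[i] == "+") {
      bs[i] <- max(tss$tss[i] - up, 0)
      be[i] <- min(tss$tss[i] + down, len[i])
    } else {
      bs[i] <- max(tss$tss[i] - down + 1, 0)
      be[i] <- min(tss$tss[i] + up + 1, len[i])
    }
  }
  for (i in seq_len(n)) {
    lim <- max(bs[i] - maxext, 0)
    cand <- lim
    limr <- min(be[i] + maxext, len[i])
    candr <- limr
    for (j in seq_len(n)) {
      if (j == i || tss$chrom[j] != tss$chrom[i]) next
      # nearest neighboring basal boundary inside the extension limit wins
      if (be[j] <= bs[i] && be[j] > cand) cand <- be[j]
      if (bs[j] >= be[i] && bs[j] < candr) candr <- bs[j]
    }
    es[i] <- min(bs[i], cand)
    ee[i] <- max(be[i], candr)
  }
  data.frame(gene = tss$gene, chrom = tss$chrom, basal_start = bs,
             basal_end = be, ext_start = es, ext_end = ee,
             stringsAsFactors = FALSE)
}

bf_associate <- function(peaks, domains) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- peaks$start[i] + (peaks$end[i] - peaks$start[i]) %/% 2
    for (j in seq_len(nrow(domains))) {
      if (peaks$chrom[i] == domains$chrom[j] &&
          mid >= domains$ext_start[j] && mid < domains$ext_end[j]) {
        out[[length(out) + 1]] <- data.frame(
          peak = peaks$name[i], gene = domains$gene[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(peak = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$peak, res$gene, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- fixture builders ------------------------------------------------------

rand_std_peaks <- function(n, genome, seed, width = 501) {
  set.seed(seed)
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- floor(runif(n, 0, as.numeric(genome[chrom]) - width))
  data.frame(chrom = chrom, start = start, end = start + width,
             summit = start + (width - 1) / 2,
             score = rgamma(n, 2, 0.01),
             name = sprintf("p%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

rand_intervals <- function(n, genome, seed, min_w = 50, max_w = 2000) {
  set.seed(seed)
  chrom <- sample(names(genome), n, replace = TRUE)
  w <- floor(runif(n, min_w, max_w))
  start <- floor(runif(n, 0, as.numeric(genome[chrom]) - w))
  data.frame(chrom = chrom, start = start, end = start + w,
             stringsAsFactors = FALSE)
}
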