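# Synthetic inputs for the epigenome arm: per-sample peak calls sharing a
# common archetype set (so cross-sample overlaps exist by construction), a
# blacklist, negative-binomial fragment counts with planted log2
# fold-changes, binary motif x peak membership with planted condition
# motifs, and a TSS table for regulatory-domain linking.

make_blacklist <- function(genome, fraction, interval_len = 2000) {
  if (fraction <= 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  out <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    il <- min(interval_len, floor(len / 4))
    n_iv <- max(1L, ceiling(fraction * len / il))
    start <- floor(stats::runif(n_iv, 0, len - il))
    data.frame(chrom = ch, start = start, end = start + il,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
}

#' Simulate per-sample peak calls and a blacklist
#'
#' A shared set of `peaks_per_sample` summit "archetypes" is placed across
#' the genome (length-weighted, including chrY); each sample re-observes an
#' archetype with probability `prob_present`, jittered by at most `jitter`
#' bp (well under the 250 bp standardization flank, so cross-sample overlap
#' of re-observed archetypes is guaranteed), plus a fraction of
#' sample-specific noise summits. Peak scores are Gamma distributed. When a
#' blacklist is requested, two archetypes are deliberately relocated inside
#' blacklist intervals, and one archetype is forced onto chrY, so the
#' downstream filters are always exercised.
#'
#' @param genome A [toy_genome()].
#' @param n_samples Number of samples.
#' @param peaks_per_sample Number of shared archetypes (>= 1).
#' @param score_shape,score_rate Gamma parameters of the peak score.
#' @param blacklist_fraction Approximate fraction of the genome covered by
#'   blacklist intervals (0 gives an empty blacklist).
#' @param prob_present Probability a sample re-observes an archetype (the
#'   first three archetypes are present in every sample).
#' @param jitter Maximum absolute summit jitter per sample, bp.
#' @param noise_frac Sample-specific noise summits as a fraction of
#'   `peaks_per_sample`.
#' @param seed Master seed.
#' @param sample_seeds Optional per-sample seeds (defaults derived from
#'   `seed`); passing identical values makes samples identical.
#' @return List with `samples` (list of data frames `chrom`, `summit`,
#'   `score`), `blacklist` (data frame `chrom`, `start`, `end`), and
#'   `archetypes`.
#' @export
simulate_peak_samples <- function(genome, n_samples = 3L,
                                  peaks_per_sample = 50L,
                                  score_shape = 2, score_rate = 0.01,
                                  blacklist_fraction = 0.02,
                                  prob_present = 0.9, jitter = 30L,
                                  noise_frac = 0.1, seed = 1L,
                                  sample_seeds = NULL) {
  if (!inherits(genome, "toy_genome")) stop("genome must be a toy_genome")
  if (length(genome) == 0) stop("empty genome")
  if (peaks_per_sample < 1) stop("peaks_per_sample must be >= 1")
  if (n_samples < 1) stop("n_samples must be >= 1")
  margin <- 400
  if (any(genome <= 2 * margin)) stop("chromosomes too short for peak placement")

  with_seed(seed, {
    bl <- make_blacklist(genome, blacklist_fraction)
    n_arch <- as.integer(peaks_per_sample)
    chroms <- names(genome)
    a_chr <- sample(chroms, n_arch, replace = TRUE, prob = as.numeric(genome))
    a_pos <- floor(stats::runif(n_arch, margin, genome[a_chr] - margin))
    if (nrow(bl) > 0 && n_arch >= 2) {
      # plant two archetypes inside blacklist intervals
      for (i in 1:2) {
        iv <- bl[min(i, nrow(bl)), ]
        a_chr[i] <- iv$chrom
        a_pos[i] <- floor((iv$start + iv$end) / 2)
      }
    }
    if ("chrY" %in% chroms && n_arch >= 3) {
      a_chr[3] <- "chrY"
      a_pos[3] <- floor(genome[["chrY"]] / 2)
    }

    if (is.null(sample_seeds)) {
      sample_seeds <- vapply(seq_len(n_samples),
                             function(i) derive_seed(seed, "sample", i),
                             integer(1))
    }
    samples <- lapply(seq_len(n_samples), function(i) {
      with_seed(as.integer(sample_seeds[i]), {
        pres <- stats::runif(n_arch) <= prob_present
        pres[seq_len(min(3L, n_arch))] <- TRUE
        s_chr <- a_chr[pres]
        s_pos <- a_pos[pres] +
          sample(seq(-jitter, jitter), sum(pres), replace = TRUE)
        n_noise <- ceiling(noise_frac * n_arch)
        nz_chr <- sample(chroms, n_noise, replace = TRUE,
                         prob = as.numeric(genome))
        nz_pos <- floor(stats::runif(n_noise, margin, genome[nz_chr] - margin))
        df <- data.frame(chrom = c(s_chr, nz_chr),
                         summit = c(s_pos, nz_pos),
                         stringsAsFactors = FALSE)
        df$score <- stats::rgamma(nrow(df), shape = score_shape,
                                  rate = score_rate)
        df <- df[order(df$chrom, df$summit, method = "radix"), , drop = FALSE]
        rownames(df) <- NULL
        df
      })
    })
    names(samples) <- sprintf("sample%d", seq_len(n_samples))
    list(samples = samples, blacklist = bl,
         archetypes = data.frame(chrom = a_chr, summit = a_pos,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate negative-binomial fragment counts over a peak set
#'
#' Per-peak baseline abundances are log-normal; samples in the second
#' condition level have their mean multiplied by `2^planted_lfc` for the
#' planted peaks. Counts are negative binomial with variance
#' `mu + dispersion * mu^2` (the count-data convention). The per-sample
#' scaling applies the same factor to both conditions, so the planted
#' cross-condition expected ratio is exactly `2^lfc`.
#'
#' @param peakset Consensus peak data frame (needs a `name` column) or a
#'   character vector of peak names.
#' @param design Named character vector mapping sample name to condition
#'   (at most two condition levels; the first factor level is the
#'   reference).
#' @param planted_lfc Named numeric vector of log2 fold-changes keyed by
#'   peak name (unnamed full-length vectors are used as-is); missing peaks
#'   get 0.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param lib_sizes Expected library size per sample (default 2e5 each).
#' @param base_meanlog,base_sdlog Log-normal parameters of the per-peak
#'   baseline abundance.
#' @param seed Seed.
#' @return A [count_matrix()] with extra fields `conditions` (factor) and a
#'   `truth` attribute (the per-peak planted lfc vector).
#' @export
simulate_fragment_counts <- function(peakset, design, planted_lfc = NULL,
                                     dispersion = 0.1, lib_sizes = NULL,
                                     base_meanlog = log(50), base_sdlog = 1,
                                     seed = 1L) {
  pk <- if (is.character(peakset)) {
    peakset
  } else if (is.data.frame(peakset) && "name" %in% names(peakset)) {
    as.character(peakset$name)
  } else if (is.data.frame(peakset)) {
    sprintf("peak_%05d", seq_len(nrow(peakset)))
  } else {
    stop("peakset must be a data frame or character vector")
  }
  np <- length(pk)
  if (np == 0) stop("empty peak set")
  if (dispersion <= 0) stop("dispersion must be positive")
  ns <- length(design)
  if (ns < 1) stop("design must name at least one sample")
  if (is.null(names(design))) names(design) <- sprintf("sample%d", seq_len(ns))
  cond <- factor(design)
  if (nlevels(cond) > 2) stop("at most two condition levels supported")

  lfc <- stats::setNames(rep(0, np), pk)
  if (!is.null(planted_lfc)) {
    if (is.null(names(planted_lfc))) {
      if (length(planted_lfc) != np) {
        stop("unnamed planted_lfc must cover every peak")
      }
      lfc[] <- planted_lfc
    } else {
      hit <- intersect(names(planted_lfc), pk)
      lfc[hit] <- planted_lfc[hit]
    }
  }
  if (is.null(lib_sizes)) lib_sizes <- rep(2e5, ns)
  if (length(lib_sizes) != ns) stop("lib_sizes must match design length")

  with_seed(seed, {
    base <- stats::rlnorm(np, base_meanlog, base_sdlog)
    sc <- lib_sizes / sum(base)
    shift <- outer(lfc, as.integer(cond) - 1L)
    mu <- (base %o% sc) * 2^shift
    counts <- matrix(
      stats::rnbinom(np * ns, mu = mu, size = 1 / dispersion),
      np, ns, dimnames = list(pk, names(design))
    )
    cm <- count_matrix(counts)
    cm$conditions <- cond
    attr(cm, "truth") <- lfc
    cm
  })
}

#' Simulate a binary motif x peak membership matrix with GC fractions
#'
#' Background membership is Bernoulli(`match_prob`). The first
#' `planted_condition_motifs` motifs instead match the `planted_peaks` with
#' probability `planted_match_prob`, coupling those motifs to whatever
#' condition effect was planted on those peaks. Every motif is guaranteed at
#' least one matching peak. Per-peak GC fractions are Beta(5, 5).
#'
#' @param peakset Peak data frame with a `name` column, or peak names.
#' @param n_motifs Number of motifs (>= 1).
#' @param match_prob Background match probability, strictly in (0, 1).
#' @param planted_condition_motifs Number of condition-coupled motifs.
#' @param planted_peaks Indices or names of the peaks carrying the planted
#'   condition effect (required when `planted_condition_motifs > 0`).
#' @param planted_match_prob Match probability of planted motifs on planted
#'   peaks.
#' @param seed Seed.
#' @return List with `matches` (0/1 matrix, motifs x peaks, dimnames set)
#'   and `gc` (named numeric per-peak GC fraction in `[0, 1]`).
#' @export
simulate_motif_matches <- function(peakset, n_motifs = 50L, match_prob = 0.1,
                                   planted_condition_motifs = 0L,
                                   planted_peaks = NULL,
                                   planted_match_prob = 0.6, seed = 1L) {
  pk <- if (is.character(peakset)) {
    peakset
  } else {
    as.character(peakset$name)
  }
  np <- length(pk)
  if (np == 0) stop("empty peak set")
  if (n_motifs < 1) stop("n_motifs must be >= 1")
  if (match_prob <= 0 || match_prob >= 1) {
    stop("match_prob must be strictly between 0 and 1")
  }
  if (planted_condition_motifs > 0 && is.null(planted_peaks)) {
    stop("planted_peaks required when planting condition motifs")
  }
  with_seed(seed, {
    M <- matrix(stats::rbinom(n_motifs * np, 1L, match_prob), n_motifs, np)
    if (planted_condition_motifs > 0) {
      idx <- if (is.character(planted_peaks)) {
        match(planted_peaks, pk)
      } else {
        as.integer(planted_peaks)
      }
      if (anyNA(idx)) stop("planted_peaks not found in peakset")
      for (m in seq_len(planted_condition_motifs)) {
        M[m, idx] <- stats::rbinom(length(idx), 1L, planted_match_prob)
      }
    }
    empty <- rowSums(M) == 0
    if (any(empty)) {
      M[cbind(which(empty), sample.int(np, sum(empty), replace = TRUE))] <- 1L
    }
    rn <- sprintf("motif%03d", seq_len(n_motifs))
    if (planted_condition_motifs > 0) {
      rn[seq_len(planted_condition_motifs)] <-
        sprintf("plantedMotif%d", seq_len(planted_condition_motifs))
    }
    dimnames(M) <- list(rn, pk)
    gc <- stats::setNames(stats::rbeta(np, 5, 5), pk)
    list(matches = M, gc = gc)
  })
}

#' Simulate a TSS table
#'
#' Places `n_genes` transcription start sites uniformly across the genome
#' (length-weighted) with ~50/50 strand assignment and unique names, sorted
#' by chromosome and position.
#'
#' @param genome A [toy_genome()].
#' @param n_genes Number of genes (>= 1).
#' @param seed Seed.
#' @return Data frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
simulate_gene_models <- function(genome, n_genes = 20L, seed = 1L) {
  if (!inherits(genome, "toy_genome")) stop("genome must be a toy_genome")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (sum(genome) < 10 * n_genes) stop("genome too small to place genes")
  with_seed(seed, {
    chr <- sample(names(genome), n_genes, replace = TRUE,
                  prob = as.numeric(genome))
    tss <- floor(stats::runif(n_genes, 0, genome[chr]))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    df <- data.frame(gene = sprintf("gene%03d", seq_len(n_genes)),
                     chrom = chr, tss = tss, strand = strand,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$tss, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}
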