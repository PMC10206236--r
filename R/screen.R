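# The prognostic gene screen: expression filters -> per-gene mixture
# stratification -> group-size filter -> multi-group log-rank selection.
# Stage thresholds default to the conventional values used for cohort
# screens of this kind: mean and variance >= 0.5 on the log2(FPKM+1) scale,
# at least two groups of >= 10 patients, and log-rank p < 0.01 on the raw
# (uncorrected) p-value, with BH q-values reported as a non-selecting
# side column.

#' Filter genes by mean and variance of expression
#'
#' Keeps a gene iff its mean is at least `mean_min` AND its variance
#' (denominator `n - 1`) is at least `var_min`. Input order is preserved.
#'
#' @param x An [expression_cohort()] or a gene x patient numeric matrix.
#' @param mean_min,var_min Inclusive thresholds (defaults 0.5 and 0.5).
#' @return Character vector of kept gene names, with a `stats` attribute
#'   (data frame of per-gene mean, variance, and keep flag).
#' @export
filter_genes <- function(x, mean_min = 0.5, var_min = 0.5) {
  m <- if (inherits(x, "expression_cohort")) x$expr else as.matrix(x)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty cohort")
  mu <- rowMeans(m)
  v <- row_vars(m)
  keep <- mu >= mean_min & v >= var_min
  keep[is.na(keep)] <- FALSE
  out <- rownames(m)[keep]
  attr(out, "stats") <- data.frame(
    gene = rownames(m), mean_expr = mu, var_expr = v, keep = keep,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Screen a single gene for prognostic stratification
#'
#' Runs the full per-gene flow: expression filter, BIC mixture-model
#' selection, the group-size rule ("at least two groups each containing at
#' least `min_group_size` patients"), and the log-rank comparison of the
#' surviving groups. By default groups smaller than `min_group_size` are
#' excluded from the survival comparison rather than disqualifying the gene
#' (`small_groups = "keep"` compares all groups once the size rule passes).
#'
#' @param expr Expression values for one gene, aligned with `time`/`event`.
#' @param time,event Survival data (see [logrank_test()]).
#' @param gene Optional gene name recorded in the output.
#' @param mean_min,var_min Expression-filter thresholds.
#' @param k_range,restarts Passed to [select_model()].
#' @param min_group_size Minimum patients per group (default 10).
#' @param p_threshold Log-rank selection threshold on the raw p (default 0.01).
#' @param small_groups `"drop"` (default) excludes undersized groups from the
#'   log-rank test; `"keep"` compares all fitted groups.
#' @param seed Optional seed for the mixture restarts.
#' @return One-row data frame (a "screen record"): `gene`, `mean_expr`,
#'   `var_expr`, `passed_expr_filter`, `k`, `group_sizes` ("/"-separated),
#'   `passed_group_filter`, `logrank_chi2`, `logrank_p`, `selected`,
#'   `reason`.
#' @export
screen_gene <- function(expr, time, event, gene = NA_character_,
                        mean_min = 0.5, var_min = 0.5,
                        k_range = 1:9, restarts = 2L,
                        min_group_size = 10L, p_threshold = 0.01,
                        small_groups = c("drop", "keep"), seed = NULL) {
  small_groups <- match.arg(small_groups)
  if (length(expr) != length(time)) stop("expr and survival must align")
  m <- mean(expr)
  v <- stats::var(expr)
  rec <- data.frame(
    gene = gene, mean_expr = m, var_expr = v,
    passed_expr_filter = isTRUE(m >= mean_min && v >= var_min),
    k = NA_integer_, group_sizes = NA_character_,
    passed_group_filter = FALSE,
    logrank_chi2 = NA_real_, logrank_p = NA_real_,
    selected = FALSE, reason = "", stringsAsFactors = FALSE
  )
  if (!rec$passed_expr_filter) {
    rec$reason <- "expression_filter"
    return(rec)
  }
  fit <- tryCatch(
    select_model(expr, k_range = k_range, restarts = restarts, seed = seed),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    rec$reason <- "degenerate_fit"
    return(rec)
  }
  rec$k <- fit$k
  sizes <- tabulate(fit$assignments, fit$k)
  rec$group_sizes <- paste(sizes, collapse = "/")
  if (fit$k < 2L) {
    rec$reason <- "single_group"
    return(rec)
  }
  big <- which(sizes >= min_group_size)
  rec$passed_group_filter <- length(big) >= 2L
  if (!rec$passed_group_filter) {
    rec$reason <- "group_size_filter"
    return(rec)
  }
  keep <- if (small_groups == "drop") {
    fit$assignments %in% big
  } else {
    rep(TRUE, length(expr))
  }
  lr <- tryCatch(
    logrank_test(time[keep], event[keep], fit$assignments[keep]),
    error = function(e) NULL
  )
  if (is.null(lr)) {
    rec$reason <- "no_events"
    return(rec)
  }
  rec$logrank_chi2 <- lr$chi2
  rec$logrank_p <- lr$p
  rec$selected <- is.finite(lr$p) && lr$p < p_threshold
  rec$reason <- if (rec$selected) "selected" else "logrank_threshold"
  rec
}

#' Run the prognostic screen over a cohort
#'
#' Applies [filter_genes()] and then [screen_gene()] to every surviving
#' gene, producing one record per gene (including filtered-out genes) plus
#' monotone stage tallies. Per-gene seeds are derived from the global seed
#' and the gene name, so results are invariant to gene and patient
#' reordering. BH-adjusted q-values over the tested log-rank p-values are
#' reported as column `logrank_q`; selection uses the raw p only.
#'
#' @param cohort An [expression_cohort()].
#' @inheritParams screen_gene
#' @param seed Global seed for the per-gene mixture restarts.
#' @return Object of class `screen_table`: list with `records` (data frame
#'   of screen records), `tallies` (named counts: genes, expr_filter,
#'   multi_group, group_size, selected), and `params`.
#' @export
run_screen <- function(cohort, mean_min = 0.5, var_min = 0.5,
                       k_range = 1:9, restarts = 2L,
                       min_group_size = 10L, p_threshold = 0.01,
                       small_groups = c("drop", "keep"), seed = 1L) {
  if (!inherits(cohort, "expression_cohort")) {
    stop("cohort must be an expression_cohort")
  }
  small_groups <- match.arg(small_groups)
  genes <- rownames(cohort$expr)
  time <- cohort$survival$time
  event <- cohort$survival$event

  recs <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    recs[[i]] <- screen_gene(
      cohort$expr[i, ], time, event, gene = genes[i],
      mean_min = mean_min, var_min = var_min,
      k_range = k_range, restarts = restarts,
      min_group_size = min_group_size, p_threshold = p_threshold,
      small_groups = small_groups,
      seed = derive_seed(seed, "gene", genes[i])
    )
  }
  records <- do.call(rbind, recs)
  records$logrank_q <- NA_real_
  tested <- !is.na(records$logrank_p)
  if (any(tested)) {
    records$logrank_q[tested] <- bh_adjust(records$logrank_p[tested])
  }

  tallies <- c(
    genes = nrow(records),
    expr_filter = sum(records$passed_expr_filter),
    multi_group = sum(records$passed_expr_filter & !is.na(records$k) &
                        records$k >= 2L),
    group_size = sum(records$passed_group_filter),
    selected = sum(records$selected)
  )
  structure(list(
    records = records,
    tallies = tallies,
    params = list(mean_min = mean_min, var_min = var_min, k_range = k_range,
                  restarts = restarts, min_group_size = min_group_size,
                  p_threshold = p_threshold, small_groups = small_groups,
                  seed = seed)
  ), class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  t <- x$tallies
  cat("Prognostic screen\n")
  cat(sprintf("  genes in:                 %d\n", t[["genes"]]))
  cat(sprintf("  pass expression filter:   %d\n", t[["expr_filter"]]))
  cat(sprintf("  stratify into >=2 groups: %d\n", t[["multi_group"]]))
  cat(sprintf("  pass group-size filter:   %d\n", t[["group_size"]]))
  cat(sprintf("  selected (log-rank p < %g): %d\n",
              x$params$p_threshold, t[["selected"]]))
  invisible(x)
}
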