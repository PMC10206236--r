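# Expression cohort container: a gene x patient matrix of log2(FPKM+1)
# values aligned 1:1 with per-patient overall-survival annotations.

#' Construct an expression cohort
#'
#' Bundles a gene x patient expression matrix (log2(FPKM+1) scale) with
#' per-patient survival time and event indicator, enforcing 1:1 alignment
#' and the absence of missing values.
#'
#' @param expr Numeric matrix, genes in rows, patients in columns.
#' @param time Nonnegative follow-up time per patient.
#' @param event Event indicator per patient (1 = death observed,
#'   0 = censored).
#' @param patients Patient identifiers; defaults to `colnames(expr)`.
#' @return An object of class `expression_cohort`: list with `expr` (matrix)
#'   and `survival` (data frame `patient`, `time`, `event`).
#' @export
expression_cohort <- function(expr, time, event, patients = colnames(expr)) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expr must be numeric")
  if (ncol(expr) != length(time) || length(time) != length(event)) {
    stop("expr columns and survival rows must align 1:1")
  }
  if (anyNA(expr) || anyNA(time) || anyNA(event)) {
    stop("missing values are not allowed in a cleaned cohort")
  }
  event <- check_surv_input(time, event)
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("gene%05d", seq_len(nrow(expr)))
  }
  if (is.null(patients)) patients <- sprintf("patient%04d", seq_len(ncol(expr)))
  colnames(expr) <- patients
  structure(list(
    expr = expr,
    survival = data.frame(patient = patients, time = as.numeric(time),
                          event = event, stringsAsFactors = FALSE)
  ), class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("Expression cohort: %d genes x %d patients, %d events (%.1f%% censored)\n",
              nrow(x$expr), ncol(x$expr), sum(x$survival$event),
              100 * mean(x$survival$event == 0)))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' Describes a synthetic tumor cohort: `n_planted_genes` prognostic genes
#' whose expression follows a shared mixture-of-Gaussians patient grouping
#' with group-dependent survival hazards, plus `n_null_genes` unimodal
#' genes independent of survival.
#'
#' Survival times are exponential: a patient in mixture component `c`
#' (components ordered by ascending mean, so higher expression means higher
#' hazard) has rate `baseline_hazard * hazard_ratio_per_group^(c - 1)`.
#' Censoring is independent exponential with its rate chosen so the expected
#' censoring fraction is approximately `censoring_rate`.
#'
#' @param n_patients Number of patients.
#' @param n_null_genes Number of unimodal non-prognostic genes.
#' @param n_planted_genes Number of mixture-expressed prognostic genes.
#' @param planted_component_means Component means (log2(FPKM+1) units).
#' @param planted_component_sds Component standard deviations (positive).
#' @param planted_mixing_weights Mixing weights (must sum to 1).
#' @param hazard_ratio_per_group Multiplicative hazard between adjacent
#'   expression groups (1 = survival independent of grouping).
#' @param baseline_hazard Event rate of the lowest-expression group
#'   (events per time unit).
#' @param censoring_rate Target censoring fraction in `[0, 1)`.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L,
                          n_null_genes = 2000L,
                          n_planted_genes = 20L,
                          planted_component_means = c(1, 3.4),
                          planted_component_sds = c(0.8, 0.8),
                          planted_mixing_weights = c(0.5, 0.5),
                          hazard_ratio_per_group = 3,
                          baseline_hazard = 0.1,
                          censoring_rate = 0.3,
                          seed = 1L) {
  kc <- length(planted_component_means)
  if (length(planted_component_sds) != kc ||
      length(planted_mixing_weights) != kc) {
    stop("component means, sds and weights must have equal length")
  }
  if (abs(sum(planted_mixing_weights) - 1) > 1e-8) {
    stop("mixing weights must sum to 1")
  }
  if (any(planted_mixing_weights < 0)) stop("mixing weights must be nonnegative")
  if (any(planted_component_sds <= 0)) stop("component sds must be positive")
  if (hazard_ratio_per_group <= 0) stop("hazard_ratio_per_group must be positive")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)")
  }
  if (n_planted_genes + n_null_genes < 1) stop("need at least one gene")
  if (n_patients < 1) stop("need at least one patient")
  structure(list(
    n_patients = as.integer(n_patients),
    n_null_genes = as.integer(n_null_genes),
    n_planted_genes = as.integer(n_planted_genes),
    planted_component_means = as.numeric(planted_component_means),
    planted_component_sds = as.numeric(planted_component_sds),
    planted_mixing_weights = as.numeric(planted_mixing_weights),
    hazard_ratio_per_group = hazard_ratio_per_group,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate an expression cohort with survival ground truth
#'
#' Draws one latent mixture component per patient (shared by every planted
#' gene, so all planted genes express the same prognostic grouping), planted
#' gene values from the component Gaussians, exponential survival times with
#' group-dependent hazard, independent exponential censoring, and unimodal
#' null genes unrelated to survival. Null gene means are drawn uniformly in
#' [1, 4] and standard deviations in [0.9, 1.4] so that most null genes pass
#' the screen's expression filter and genuinely exercise the mixture and
#' log-rank stages.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (an [expression_cohort()]), `truth` (data
#'   frame: gene, class, means, sds, weights, hazard_ratio), and
#'   `patient_groups` (the latent component per patient, ordered by
#'   ascending component mean).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  with_seed(config$seed, {
    n <- config$n_patients
    ord <- order(config$planted_component_means)
    mu <- config$planted_component_means[ord]
    sdv <- config$planted_component_sds[ord]
    w <- config$planted_mixing_weights[ord]
    kc <- length(mu)

    z <- sample.int(kc, n, replace = TRUE, prob = w)

    np <- config$n_planted_genes
    planted <- matrix(0, np, n)
    for (g in seq_len(np)) {
      planted[g, ] <- stats::rnorm(n, mu[z], sdv[z])
    }

    hazard <- config$baseline_hazard * config$hazard_ratio_per_group^(z - 1)
    t_event <- stats::rexp(n, hazard)
    if (config$censoring_rate > 0) {
      c_rate <- config$censoring_rate / (1 - config$censoring_rate) *
        mean(hazard)
      t_cens <- stats::rexp(n, c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }

    nn <- config$n_null_genes
    null_mu <- stats::runif(nn, 1, 4)
    null_sd <- stats::runif(nn, 0.9, 1.4)
    nulls <- matrix(stats::rnorm(nn * n, rep(null_mu, n), rep(null_sd, n)),
                    nn, n)

    expr <- rbind(planted, nulls)
    rownames(expr) <- c(
      if (np > 0) sprintf("plantedGene%03d", seq_len(np)) else character(0),
      if (nn > 0) sprintf("nullGene%04d", seq_len(nn)) else character(0)
    )
    colnames(expr) <- sprintf("patient%04d", seq_len(n))

    truth <- data.frame(
      gene = rownames(expr),
      class = rep(c("planted", "null"), c(np, nn)),
      means = c(rep(paste(signif(mu, 6), collapse = ","), np),
                as.character(signif(null_mu, 6))),
      sds = c(rep(paste(signif(sdv, 6), collapse = ","), np),
              as.character(signif(null_sd, 6))),
      weights = c(rep(paste(signif(w, 6), collapse = ","), np),
                  rep("1", nn)),
      hazard_ratio = rep(c(config$hazard_ratio_per_group, 1), c(np, nn)),
      stringsAsFactors = FALSE
    )

    list(
      cohort = expression_cohort(expr, time, event),
      truth = truth,
      patient_groups = z
    )
  })
}
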