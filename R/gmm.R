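# Univariate Gaussian mixture models with component-specific variances,
# fitted by EM, with BIC model selection. This is the stratification engine
# of the prognostic screen: each gene's expression vector is decomposed into
# k Gaussian groups and patients are assigned to the group with the highest
# posterior responsibility. The EM iteration itself runs in C++
# (src/gmm_em.cpp) because the screen fits tens of thousands of mixtures;
# gmm_estep/gmm_mstep below are the pure-R reference updates, used for
# initialization and as an independent oracle in the tests.

gmm_estep <- function(x, w, mu, v) {
  k <- length(w)
  lg <- matrix(0, length(x), k)
  for (j in seq_len(k)) {
    lg[, j] <- stats::dnorm(x, mu[j], sqrt(v[j]), log = TRUE) + log(w[j])
  }
  m <- lg[, 1L]
  if (k > 1L) {
    for (j in 2:k) m <- pmax(m, lg[, j])
  }
  p <- exp(lg - m)
  s <- rowSums(p)
  list(ll = sum(m + log(s)), resp = p / s)
}

gmm_mstep <- function(x, resp, variance_floor) {
  nk <- pmax(colSums(resp), 1e-12)
  mu <- colSums(resp * x) / nk
  v <- colSums(resp * (outer(x, mu, "-"))^2) / nk
  list(w = nk / length(x), mu = mu, v = pmax(v, variance_floor))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Components have free weights, means, and variances (the unequal-variance
#' family). Convergence is declared when the relative change of the
#' log-likelihood falls below `tol`; the log-likelihood sequence is
#' guaranteed nondecreasing and retained in the returned object. Components
#' are relabelled in ascending order of their means, so group 1 is always
#' the lowest-expression group.
#'
#' @param x Numeric vector of observations (finite values only).
#' @param k Number of mixture components (`>= 1`, at most `length(x)`).
#' @param init `"quantile"` places the initial means at k evenly spaced
#'   sample quantiles with equal weights and pooled variance (deterministic);
#'   `"random"` starts from random responsibilities.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param variance_floor Lower bound applied to every component variance each
#'   M-step; defaults to `1e-6` times the overall (maximum-likelihood) sample
#'   variance. Blocks singular one-point components.
#' @param seed Optional seed for the random initialization.
#'
#' @return An object of class `gmm_fit`: a list with elements `k`, `weights`,
#'   `means`, `variances`, `loglik`, `bic` (`2*loglik - (3k-1)*log(n)`,
#'   larger is better), `n`, `assignments` (maximum-responsibility labels in
#'   `1..k`, ties to the lower label), `responsibilities` (n x k,
#'   row-stochastic), `loglik_trace`, `converged`, `iterations`, and
#'   `degenerate` (`TRUE` when any fitted weight falls below `2/n`).
#'
#' @examples
#' x <- c(rnorm(100, 0, 0.5), rnorm(100, 5, 0.5))
#' fit <- fit_gmm_em(x, k = 2)
#' fit$means
#' @export
fit_gmm_em <- function(x, k, init = c("quantile", "random"), tol = 1e-8,
                       max_iter = 1000L, variance_floor = NULL, seed = NULL) {
  init <- match.arg(init)
  if (!is.numeric(x)) stop("x must be numeric")
  if (!all(is.finite(x))) stop("x must contain only finite values")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  n <- length(x)
  if (n < k) stop("fewer observations than components")
  v_all <- mean((x - mean(x))^2)
  if (v_all == 0 && k >= 2L) {
    stop("degenerate fit: all observations identical")
  }
  if (is.null(variance_floor)) {
    variance_floor <- max(1e-6 * v_all, 1e-12)
  }

  with_seed(seed, {
    if (init == "quantile" || k == 1L) {
      w <- rep(1 / k, k)
      mu <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                       names = FALSE, type = 7))
      v <- rep(max(v_all, variance_floor), k)
    } else {
      resp0 <- matrix(stats::rexp(n * k), n, k)
      resp0 <- resp0 / rowSums(resp0)
      ms <- gmm_mstep(x, resp0, variance_floor)
      w <- ms$w
      mu <- ms$mu
      v <- ms$v
    }

    em <- .gmm_em_cpp(x, w, mu, v, tol, as.integer(max_iter), variance_floor)
    w <- em$w
    mu <- em$mu
    v <- em$v
    resp <- em$resp
    ll <- em$loglik
    trace <- em$trace
    converged <- em$converged
    it <- em$iterations

    ord <- order(mu)
    w <- w[ord]
    mu <- mu[ord]
    v <- v[ord]
    resp <- resp[, ord, drop = FALSE]

    m_par <- 3L * k - 1L
    structure(list(
      k = k,
      weights = w,
      means = mu,
      variances = v,
      loglik = ll,
      bic = 2 * ll - m_par * log(n),
      n = n,
      assignments = max.col(resp, ties.method = "first"),
      responsibilities = resp,
      loglik_trace = trace,
      converged = converged,
      iterations = it,
      degenerate = (k >= 2L && any(w < 2 / n))
    ), class = "gmm_fit")
  })
}

#' Select the number of mixture components by BIC
#'
#' Fits every k in `k_range` with one deterministic quantile initialization
#' plus `restarts - 1` random-responsibility initializations, keeps the best
#' log-likelihood per k, discards degenerate fits (any weight below `2/n`),
#' and returns the fit maximizing `BIC = 2*loglik - (3k-1)*log(n)`. Exact
#' BIC ties are resolved toward the smaller k.
#'
#' @param x Numeric vector of observations.
#' @param k_range Candidate component counts (default `1:9`, a conventional
#'   grid; the maximum must not exceed `length(x)`).
#' @param restarts Independent initializations per k (>= 1).
#' @param seed Optional seed; restart sub-seeds are derived deterministically.
#'
#' @return The winning `gmm_fit` (see [fit_gmm_em()]).
#' @export
select_model <- function(x, k_range = 1:9, restarts = 3L, seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 1L || any(k_range < 1L)) {
    stop("k_range must contain positive integers")
  }
  if (max(k_range) > length(x)) {
    stop("max(k_range) exceeds the number of observations")
  }
  restarts <- max(1L, as.integer(restarts))

  best_fit <- NULL
  best_bic <- -Inf
  for (k in k_range) {
    cand <- NULL
    for (r in seq_len(restarts)) {
      s <- if (is.null(seed)) NULL else derive_seed(seed, "k", k, "r", r)
      f <- tryCatch(
        fit_gmm_em(x, k,
                   init = if (r == 1L) "quantile" else "random",
                   seed = s),
        error = function(e) NULL
      )
      if (!is.null(f) && (is.null(cand) || f$loglik > cand$loglik)) {
        cand <- f
      }
    }
    if (is.null(cand) || cand$degenerate) next
    # strict > keeps the smaller k on exact ties (k_range is ascending)
    if (cand$bic > best_bic) {
      best_bic <- cand$bic
      best_fit <- cand
    }
  }
  if (is.null(best_fit)) stop("all candidate fits degenerate")
  best_fit
}

#' Assign observations to mixture components
#'
#' Labels each observation with the component of maximum posterior
#' responsibility under the fitted parameters; exact posterior ties go to
#' the lower label. Deterministic given the fit.
#'
#' @param fit A `gmm_fit` object.
#' @param x Numeric vector to classify.
#' @return Integer labels in `1..fit$k`.
#' @export
classify <- function(fit, x) {
  if (!inherits(fit, "gmm_fit")) stop("fit must be a gmm_fit")
  if (!all(is.finite(x))) stop("x must contain only finite values")
  lg <- matrix(0, length(x), fit$k)
  for (j in seq_len(fit$k)) {
    lg[, j] <- stats::dnorm(x, fit$means[j], sqrt(fit$variances[j]),
                            log = TRUE) + log(fit$weights[j])
  }
  max.col(lg, ties.method = "first")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d, n = %d, loglik = %.4f, BIC = %.4f\n",
              x$k, x$n, x$loglik, x$bic))
  cat("  weights:  ", paste(signif(x$weights, 4), collapse = " "), "\n")
  cat("  means:    ", paste(signif(x$means, 4), collapse = " "), "\n")
  cat("  variances:", paste(signif(x$variances, 4), collapse = " "), "\n")
  cat("  group sizes:", paste(tabulate(x$assignments, x$k), collapse = "/"), "\n")
  invisible(x)
}
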