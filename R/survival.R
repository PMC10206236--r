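# Product-limit (Kaplan-Meier) estimation and the k-sample log-rank test,
# used to compare overall survival between mixture-defined patient groups.
# Both are implemented directly (the survival package serves only as an
# independent oracle in the test suite).

check_surv_input <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (length(time) < 1L) stop("need at least one subject")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and nonnegative")
  }
  event <- as.integer(event)
  if (any(is.na(event)) || !all(event %in% c(0L, 1L))) {
    stop("event must be 0 (censored) or 1 (death observed)")
  }
  event
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the step-function survival estimate
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct times. Rows where
#' only censoring occurs carry a factor of 1 (no step) but still shrink the
#' risk set for later times; censored subjects tied with an event time are
#' kept at risk for that time's events (the standard convention).
#'
#' @param time Nonnegative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @return A data frame of class `km_fit` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, one row per distinct observed time.
#' @examples
#' km_estimate(c(2, 3, 4, 4, 5), c(1, 0, 1, 1, 0))
#' @export
km_estimate <- function(time, event) {
  event <- check_surv_input(time, event)
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  cen <- vapply(ut, function(t) sum(time == t & event == 0L), numeric(1))
  out <- data.frame(
    time = ut,
    n_risk = n_risk,
    n_event = d,
    n_censor = cen,
    survival = cumprod(1 - d / n_risk)
  )
  structure(out, class = c("km_fit", "data.frame"), n = length(time))
}

#' Multi-group log-rank test
#'
#' The classical k-sample log-rank test: at each distinct event time the
#' per-group observed event counts are compared with their expectation under
#' multivariate hypergeometric sampling from the pooled risk set, and the
#' chi-square statistic is the quadratic form of the summed
#' observed-minus-expected vector (one group dropped) with the summed
#' hypergeometric covariance. Ties are handled by the multivariate
#' hypergeometric variance; the p-value is asymptotic on `k - 1` degrees of
#' freedom.
#'
#' @param time Nonnegative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @param group Group labels (any atomic type); every group must be
#'   non-empty and at least two groups are required.
#' @return An object of class `logrank_test`: list with `chi2`, `df`
#'   (`= k - 1`), `p`, plus per-group `observed` and `expected` event counts.
#' @examples
#' logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(c("a", "b"), each = 3))
#' @export
logrank_test <- function(time, event, group) {
  event <- check_surv_input(time, event)
  if (length(group) != length(time)) stop("group length differs from time")
  g <- droplevels(factor(group))
  k <- nlevels(g)
  if (k < 2L) stop("need at least two non-empty groups")
  if (sum(event) < 1L) stop("log-rank test undefined with zero observed events")

  ut <- sort(unique(time[event == 1L]))
  nt_mat <- vapply(levels(g), function(l) {
    st <- sort(time[g == l])
    length(st) - findInterval(ut, st, left.open = TRUE)
  }, numeric(length(ut)))
  nt_mat <- matrix(nt_mat, nrow = length(ut), ncol = k)
  d_mat <- unclass(table(factor(time[event == 1L], levels = ut),
                         g[event == 1L]))
  d_mat <- matrix(as.numeric(d_mat), nrow = length(ut), ncol = k)

  nt <- rowSums(nt_mat)
  dt <- rowSums(d_mat)
  P <- nt_mat / nt
  O <- colSums(d_mat)
  E <- colSums(dt * P)
  cfac <- ifelse(nt > 1, dt * (nt - dt) / (nt - 1), 0)
  V <- diag(colSums(cfac * P), k) - t(P) %*% (P * cfac)

  oe <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(
    drop(crossprod(oe, solve(Vk, oe))),
    error = function(e) {
      sv <- svd(Vk)
      pos <- sv$d > max(sv$d, 0) * 1e-12
      if (!any(pos)) return(0)
      drop(crossprod(oe, sv$v[, pos, drop = FALSE] %*%
                       ((crossprod(sv$u[, pos, drop = FALSE], oe)) / sv$d[pos])))
    }
  )
  chi2 <- max(chi2, 0)
  df <- k - 1L
  structure(list(
    chi2 = chi2,
    df = df,
    p = stats::pchisq(chi2, df, lower.tail = FALSE),
    observed = stats::setNames(O, levels(g)),
    expected = stats::setNames(E, levels(g))
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}
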