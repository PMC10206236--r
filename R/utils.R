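# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded simulators do not
#' perturb the global stream. A `NULL` seed evaluates the code as-is.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic 31-adic string hash into [0, 2^31 - 2]. Used to derive
# per-gene / per-sample sub-seeds that are stable under input reordering.
hash32 <- function(x) {
  m <- 2147483647
  vapply(as.character(x), function(s) {
    h <- 0
    for (v in utf8ToInt(enc2utf8(s))) h <- (h * 31 + v) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

derive_seed <- function(seed, ...) {
  as.integer(hash32(paste(seed, ..., sep = "/")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row variances with denominator n - 1 (matching stats::var).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) {
    return(rep(NA_real_, nrow(x)))
  }
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
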