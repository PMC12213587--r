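`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Deterministic cross-validation fold assignment
#'
#' Assigns each of `n` observations to one of `k` folds, balanced to within
#' one observation, using an isolated RNG stream so the caller's random state
#' is untouched.
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed controlling the assignment.
#' @return integer vector of length `n` with values in `1:k`.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 1 || k > n) .stopf("need 1 <= k <= n, got k=%d, n=%d", k, n)
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

## column-mean imputation of a dosage matrix; all-missing columns become 0
.impute_mean <- function(X) {
  X <- matrix(as.numeric(X), nrow = nrow(X), dimnames = dimnames(X))
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    X[nas] <- mu[nas[, 2L]]
  }
  X
}

## squared Pearson correlation that tolerates constant vectors (returns 0)
.safe_r2 <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)^2
}
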