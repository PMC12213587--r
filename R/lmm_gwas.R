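#' Fit the null linear mixed model for association scanning
#'
#' Fits `y = X b + g + e`, `g ~ N(0, K sigma_g2)` by spectral REML and caches
#' the eigen-rotation so that individual markers can be scored cheaply with
#' the variance ratio held fixed at its null estimate (the EMMAX
#' approximation).
#'
#' @param y phenotype vector (training samples).
#' @param K kinship / relationship matrix from the full marker set on the
#'   same samples.
#' @param X covariate matrix; an intercept column is prepended when absent.
#'   The conventional design is intercept + 3 genotype PCs
#'   ([pca_covariates()]).
#' @return list of class `lmm_null` caching the rotation, the REML fit and
#'   the whitened covariates.
#' @export
fit_null_lmm <- function(y, K, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (!any(apply(X, 2L, function(c) stats::sd(c) == 0 && c[1L] != 0)))
    X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) {
    r <- qr(X)
    drop_cols <- setdiff(seq_len(ncol(X)), r$pivot[seq_len(r$rank)])
    .stopf("collinear covariate column(s): %s",
           paste(colnames(X)[drop_cols] %||% drop_cols, collapse = ", "))
  }
  eg <- .grm_eigen(K)
  vc <- reml_h2(y, K, X = X, eigen_G = eg)
  w <- 1 / sqrt(eg$values + vc$delta)
  Ut <- t(eg$vectors)
  ys <- drop(Ut %*% y) * w
  Xs <- (Ut %*% X) * w
  qrX <- qr(Xs)
  structure(list(vc = vc, Ut = Ut, w = w, ys = ys, Xs = Xs, qrX = qrX,
                 n = n, p = ncol(X)),
            class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf("null LMM fit: n = %d, %d covariate(s), h2 = %.3f, logLik %.2f\n",
              x$n, x$p, x$vc$h2, x$vc$loglik))
  invisible(x)
}

#' Score markers against a fitted null model
#'
#' For each marker, a generalized-least-squares slope test in the whitened
#' space of the null fit: the marker column is rotated and whitened, both it
#' and the phenotype are residualized on the covariates, and a two-sided
#' Wald (t) test of the slope is reported. Monomorphic markers, and markers
#' collinear with the covariates, get `beta = 0`, `p = 1`.
#'
#' @param geno a [genotype_matrix()] over the same samples (and order) used
#'   in [fit_null_lmm()].
#' @param null_fit an `lmm_null` object.
#' @param marker_scope optional marker ids restricting the scan.
#' @param exact when `TRUE`, the variance ratio is re-estimated by REML for
#'   every marker (the marker joins the fixed effects) instead of being held
#'   at the null estimate. Orders of magnitude slower; the approximation is
#'   the default for the optimizer's inner loop.
#' @return `data.frame` of class `gwas_result` with `marker_id`, `chrom`,
#'   `pos`, `beta`, `se`, `p`.
#' @export
score_markers <- function(geno, null_fit, marker_scope = NULL, exact = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(null_fit, "lmm_null"))
  idx <- if (is.null(marker_scope)) seq_len(ncol(geno$dosages))
         else sort(match(marker_scope, geno$markers$id))
  if (anyNA(idx)) .stopf("marker_scope contains unknown ids")
  if (nrow(geno$dosages) != null_fit$n)
    .stopf("genotype matrix and null fit cover different sample counts")
  M <- .impute_mean(geno$dosages[, idx, drop = FALSE])
  if (exact) return(.score_markers_exact(geno, null_fit, idx, M))
  Ms <- (null_fit$Ut %*% M) * null_fit$w
  ## residualize on the whitened covariates
  Mr <- qr.resid(null_fit$qrX, Ms)
  yr <- qr.resid(null_fit$qrX, null_fit$ys)
  xx <- colSums(Mr^2)
  xy <- drop(crossprod(Mr, yr))
  yy <- sum(yr^2)
  df <- null_fit$n - null_fit$p - 1L
  ok <- xx > 1e-10 * max(xx, 1)
  beta <- ifelse(ok, xy / xx, 0)
  rss <- pmax(yy - beta * xy, 0)
  se <- ifelse(ok, sqrt(rss / df / xx), NA_real_)
  tval <- ifelse(ok & se > 0, beta / se, 0)
  p <- 2 * stats::pt(-abs(tval), df = df)
  p[!ok] <- 1
  if (any(!ok))
    message(sprintf("score_markers: %d monomorphic/collinear marker(s) set to p = 1", sum(!ok)))
  out <- data.frame(marker_id = geno$markers$id[idx],
                    chrom = geno$markers$chrom[idx],
                    pos = geno$markers$pos[idx],
                    beta = beta, se = se, p = pmin(pmax(p, .Machine$double.xmin), 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gwas_result", "data.frame")
  out
}

## exact Wald test: per-marker REML refit with the marker as a fixed effect
.score_markers_exact <- function(geno, null_fit, idx, M) {
  n <- null_fit$n
  U <- t(null_fit$Ut)
  D <- 1 / null_fit$w^2 - null_fit$vc$delta   # recover eigenvalues
  X0 <- U %*% null_fit$Xs / null_fit$w        # un-whiten the covariates
  y <- drop(U %*% (null_fit$ys / null_fit$w))
  p1 <- ncol(X0) + 1L
  out <- t(vapply(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    if (stats::sd(x) == 0) return(c(0, NA_real_, 1))
    X <- cbind(X0, x)
    if (qr(X)$rank < p1) return(c(0, NA_real_, 1))
    fit <- .reml_spectral(y, X, U, D)
    v <- D + fit$delta
    Xt <- crossprod(U, X)
    XtWX <- crossprod(Xt, Xt / v)
    se <- sqrt(fit$sigma_g2 * solve(XtWX)[p1, p1])
    tval <- fit$beta[p1] / se
    c(fit$beta[p1], se, 2 * stats::pt(-abs(tval), df = n - p1))
  }, numeric(3L)))
  res <- data.frame(marker_id = geno$markers$id[idx],
                    chrom = geno$markers$chrom[idx],
                    pos = geno$markers$pos[idx],
                    beta = out[, 1L], se = out[, 2L],
                    p = pmin(pmax(out[, 3L], .Machine$double.xmin), 1),
                    stringsAsFactors = FALSE)
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Write an association table as TSV
#'
#' @param gwas a `gwas_result` from [score_markers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
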