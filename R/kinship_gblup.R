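#' Genomic relationship matrix
#'
#' VanRaden method 1: `G = W W' / (2 * sum(p_j (1 - p_j)))` where `W` is the
#' dosage matrix centered by twice the observed allele frequency `2 p_j`.
#' Missing dosages are mean-imputed per marker (which centers them to zero).
#' The `"gcta"` variant standardizes each centered column by
#' `sqrt(2 p_j (1 - p_j))` and divides by the number of polymorphic markers.
#'
#' @param geno a [genotype_matrix()] or a samples x markers dosage matrix.
#' @param method `"vanraden1"` (default) or `"gcta"`.
#' @return symmetric `n x n` matrix with sample ids as dimnames.
#' @export
build_grm <- function(geno, method = c("vanraden1", "gcta")) {
  method <- match.arg(method)
  X <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  if (nrow(X) < 2L) .stopf("need at least 2 samples")
  X <- .impute_mean(X)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) .stopf("no polymorphic markers")
  W <- sweep(X[, poly, drop = FALSE], 2L, 2 * p[poly])
  if (method == "vanraden1") {
    G <- tcrossprod(W) / (2 * sum(p[poly] * (1 - p[poly])))
  } else {
    W <- sweep(W, 2L, sqrt(2 * p[poly] * (1 - p[poly])), "/")
    G <- tcrossprod(W) / sum(poly)
  }
  G <- (G + t(G)) / 2
  ids <- rownames(X)
  if (!is.null(ids)) dimnames(G) <- list(ids, ids)
  G
}

## Restricted log-likelihood profile over delta = sigma_e^2 / sigma_g^2 for
## y = X b + g + e, g ~ N(0, sigma_g^2 G), using the spectral decomposition
## G = U diag(D) U'. Returns the REML estimate; among numerically tied
## profile values the largest delta wins (so that an uninformative G, e.g.
## G = I, resolves to sigma_g^2 -> 0 rather than an arbitrary split).
.reml_spectral <- function(y, X, U, D, log10_range = c(-6, 6), grid_by = 0.2) {
  n <- length(y); p <- ncol(X)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  ll_of <- function(delta) {
    v <- D + delta
    if (any(v <= 0)) return(-Inf)
    w <- 1 / v
    XtWX <- crossprod(Xt, Xt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    rhs <- crossprod(Xt, yt * w)
    beta <- backsolve(ch, forwardsolve(t(ch), rhs))
    r <- yt - Xt %*% beta
    q <- sum(w * r^2)
    if (q <= 0) return(-Inf)
    sg2 <- q / (n - p)
    list(ll = -0.5 * ((n - p) * (log(2 * pi) + 1 + log(sg2)) +
                        sum(log(v)) + 2 * sum(log(diag(ch)))),
         sg2 = sg2, beta = beta)
  }
  lg <- seq(log10_range[1L], log10_range[2L], by = grid_by)
  deltas <- 10^lg
  lls <- vapply(deltas, function(d) {
    f <- ll_of(d); if (is.list(f)) f$ll else f
  }, numeric(1L))
  best <- max(lls)
  if (!is.finite(best)) .stopf("restricted likelihood undefined on the whole grid")
  near <- which(lls >= best - 1e-6)
  i <- max(near)                      # flat-tie rule: largest delta
  if (length(near) < length(deltas)) {
    lo <- lg[max(1L, i - 1L)]; hi <- lg[min(length(lg), i + 1L)]
    opt <- stats::optimize(function(l) {
      f <- ll_of(10^l); if (is.list(f)) f$ll else f
    }, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (opt$objective > lls[i] + 1e-9) {
      delta <- 10^opt$maximum
    } else delta <- deltas[i]
  } else delta <- deltas[i]
  fit <- ll_of(delta)
  list(delta = delta, sigma_g2 = fit$sg2, sigma_e2 = fit$sg2 * delta,
       h2 = 1 / (1 + delta), loglik = fit$ll, beta = drop(fit$beta))
}

.grm_eigen <- function(G, tol = 1e-6) {
  eg <- eigen(G, symmetric = TRUE)
  mx <- max(abs(eg$values))
  if (min(eg$values) < -tol * max(mx, 1))
    .stopf("relationship matrix is not positive semidefinite (min eigenvalue %.3g); consider adding a small ridge", min(eg$values))
  eg$values <- pmax(eg$values, 0)
  eg
}

#' Genomic heritability by spectral REML
#'
#' Fits `y = 1 mu + g + e` with `g ~ N(0, G sigma_g^2)`,
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood, profiling the
#' variance ratio `delta = sigma_e^2 / sigma_g^2` on a log grid followed by
#' golden-section refinement (deterministic). Heritability is
#' `h^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`, which assumes `G` is scaled
#' so its diagonal is near 1.
#'
#' @param y phenotype vector, complete for the included samples.
#' @param G relationship matrix from [build_grm()] (or its eigen
#'   decomposition, see `eigen_G`).
#' @param X optional fixed-effect design matrix (defaults to an intercept).
#' @param eigen_G optional precomputed `eigen(G, symmetric = TRUE)` to reuse
#'   across traits.
#' @return list of class `varcomp` with `sigma_g2`, `sigma_e2`, `h2`,
#'   `loglik`, `delta` and the GLS fixed-effect estimates `beta`.
#' @export
reml_h2 <- function(y, G, X = NULL, eigen_G = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) .stopf("phenotype vector contains missing values")
  if (stats::var(y) == 0) .stopf("phenotype has zero variance")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (nrow(X) != n) .stopf("X has %d rows, y has %d", nrow(X), n)
  if (qr(X)$rank < ncol(X)) .stopf("fixed-effect design matrix is rank deficient (collinear columns)")
  eg <- eigen_G %||% {
    if (!is.matrix(G) || nrow(G) != n) .stopf("G must be an %d x %d matrix", n, n)
    .grm_eigen(G)
  }
  fit <- .reml_spectral(y, X, eg$vectors, eg$values)
  structure(fit[c("sigma_g2", "sigma_e2", "h2", "loglik", "delta", "beta")],
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.4f (logLik %.2f)\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$loglik))
  invisible(x)
}

#' GBLUP prediction for held-out samples
#'
#' Given a relationship matrix over all samples, estimates the variance ratio
#' by REML on the training partition only, then predicts the genetic values
#' of the test samples as
#' `mu + G[test, train] (G[train, train] + lambda I)^{-1} (y_train - mu)`
#' with `lambda = sigma_e^2 / sigma_g^2` and `mu` the GLS mean.
#'
#' @param y_train phenotypes of the training samples (order matching
#'   `train_idx`).
#' @param G relationship matrix over all samples.
#' @param train_idx,test_idx disjoint sample index vectors into `G`.
#' @param vc optional precomputed [reml_h2()] fit on the training partition;
#'   estimated when `NULL`.
#' @return numeric vector of predicted phenotypes for `test_idx`.
#' @export
gblup_fit_predict <- function(y_train, G, train_idx, test_idx, vc = NULL) {
  train_idx <- as.integer(train_idx); test_idx <- as.integer(test_idx)
  if (length(intersect(train_idx, test_idx)))
    .stopf("train and test indices overlap")
  if (length(y_train) != length(train_idx))
    .stopf("y_train length does not match train_idx")
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  if (is.null(vc)) vc <- reml_h2(y_train, Gtt)
  lambda <- if (vc$sigma_g2 <= 0) Inf else vc$sigma_e2 / vc$sigma_g2
  if (!is.finite(lambda)) lambda <- 1e12
  M <- Gtt + diag(lambda, length(train_idx))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    M <- M + diag(1e-8, nrow(M))
    message("gblup_fit_predict: singular system, applied ridge jitter 1e-8")
    ch <- chol(M)
  }
  solve_M <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  one <- rep(1, length(train_idx))
  mu <- sum(solve_M(y_train)) / sum(solve_M(one))
  alpha <- solve_M(y_train - mu)
  drop(mu + G[test_idx, train_idx, drop = FALSE] %*% alpha)
}

#' Principal-component covariates from genotypes
#'
#' Top-`k` principal-component scores of the column-centered and
#' unit-variance-scaled dosage matrix (markers with zero variance are
#' dropped). The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param geno a [genotype_matrix()] or dosage matrix (training samples only;
#'   computing PCs on all samples before splitting leaks structure).
#' @param k number of components (default 3).
#' @return `n x k` score matrix.
#' @export
pca_covariates <- function(geno, k = 3L) {
  X <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  X <- .impute_mean(X)
  sds <- apply(X, 2L, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (!ncol(X)) .stopf("no polymorphic markers; genotype matrix has rank 0 after centering")
  X <- scale(X)
  if (k >= min(dim(X))) .stopf("k = %d must be below min(n, m) = %d", k, min(dim(X)))
  sv <- svd(X, nu = k, nv = k)
  if (sv$d[k] < 1e-8 * sv$d[1L]) .stopf("requested %d components but rank is lower", k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    ld <- sv$v[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

## mean k-fold cross-validated GBLUP r^2 given a precomputed G over the
## (training) samples and a fixed fold assignment. Workhorse of the budget
## curve and the bin optimizer.
.cv_gblup_r2 <- function(G, y, folds) {
  preds <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    preds[te] <- gblup_fit_predict(y[tr], G, tr, te)
  }
  .safe_r2(y, preds)
}
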