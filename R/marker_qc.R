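#' Marker quality-control configuration
#'
#' Thresholds for the QC chain applied before any selection: minor-allele
#' frequency filter, Hardy-Weinberg equilibrium filter, then windowed LD
#' pruning. Windows are counted in SNPs, not base pairs.
#'
#' @param maf_min minimum minor allele frequency (markers below are removed).
#' @param hwe_p_min minimum Hardy-Weinberg exact-fit chi-square p-value.
#' @param ld_window sliding-window width in SNPs.
#' @param ld_step window step in SNPs.
#' @param ld_r2_max squared-correlation threshold above which one member of a
#'   pair is pruned.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, hwe_p_min = 1e-6, ld_window = 50L,
                      ld_step = 5L, ld_r2_max = 0.95) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            ld_step >= 1, ld_window > ld_step, ld_r2_max > 0, ld_r2_max <= 1)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 ld_window = as.integer(ld_window), ld_step = as.integer(ld_step),
                 ld_r2_max = ld_r2_max),
            class = "qc_config")
}

#' Per-marker minor allele frequency
#'
#' `maf = min(p, 1 - p)` with `p = mean(dosage) / 2` over non-missing calls.
#' Markers with no non-missing call get `NA` and must be excluded downstream.
#'
#' @param geno a [genotype_matrix()] or a dosage matrix.
#' @return numeric vector, one value per marker.
#' @export
compute_maf <- function(geno) {
  X <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  p <- colMeans(X, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  unname(pmin(p, 1 - p))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the proportions expected under Hardy-Weinberg equilibrium at the observed
#' allele frequency. Monomorphic markers return `p = 1` by convention.
#' Arguments are vectorized.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference hom, het, alternate hom).
#' @return p-value(s) in `(0, 1]`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) .stopf("total genotype count must be positive")
  if (any(c(n_AA, n_Aa, n_aa) < 0)) .stopf("genotype counts must be non-negative")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  o <- cbind(n_AA, n_Aa, n_aa)
  chi2 <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
  out <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1
  unname(out)
}

#' Squared-correlation linkage disequilibrium between two markers
#'
#' Squared Pearson correlation of dosages over pairwise-complete entries.
#' Returns `NA` when either vector is constant (treated as 0 by the pruner).
#'
#' @param x,y dosage vectors of equal length.
#' @return a fraction in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) .stopf("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) .stopf("need at least 2 pairwise-complete entries")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `cfg$ld_window` SNPs (advanced by `cfg$ld_step`) along
#' the coordinate-sorted markers. Within each window, while any surviving
#' pair has `r^2 > cfg$ld_r2_max`, the pair with the highest `r^2` is
#' resolved by removing its lower-MAF member (ties: the later position goes).
#' Missing dosages are mean-imputed for the correlation only. The result
#' preserves genomic order and is deterministic.
#'
#' Markers listed in `keep` are never removed; when a violating pair contains
#' a protected marker the unprotected one is pruned regardless of MAF. Pairs
#' with both members protected are left alone.
#'
#' @param geno a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @param marker_ids optional subset of marker ids to prune (defaults to all);
#'   windows are defined over this subset in genomic order.
#' @param keep optional character vector of protected marker ids.
#' @return character vector of surviving marker ids in genomic order.
#' @export
ld_prune <- function(geno, cfg = qc_config(), marker_ids = NULL, keep = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ids_all <- geno$markers$id
  idx <- if (is.null(marker_ids)) seq_along(ids_all) else sort(match(marker_ids, ids_all))
  if (anyNA(idx)) .stopf("unknown marker id(s) in marker_ids")
  m <- length(idx)
  if (m <= 1L) return(ids_all[idx])
  X <- .impute_mean(geno$dosages[, idx, drop = FALSE])
  maf <- compute_maf(geno$dosages[, idx, drop = FALSE])
  maf[is.na(maf)] <- -1  # all-missing markers lose every tie
  protected <- if (is.null(keep)) logical(m) else ids_all[idx] %in% keep
  alive <- rep(TRUE, m)
  w <- cfg$ld_window; step <- cfg$ld_step
  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    e <- min(s + w - 1L, m)
    sub <- which(alive[s:e]) + s - 1L
    if (length(sub) < 2L) next
    C <- suppressWarnings(stats::cor(X[, sub, drop = FALSE]))^2
    C[!is.finite(C)] <- 0
    diag(C) <- 0
    repeat {
      mx <- max(C)
      if (mx <= cfg$ld_r2_max) break
      hit <- which(C == mx, arr.ind = TRUE)[1L, ]  # deterministic (col-major)
      i <- sub[min(hit)]; j <- sub[max(hit)]
      victim <-
        if (protected[i] && protected[j]) NA_integer_
        else if (protected[i]) j
        else if (protected[j]) i
        else if (maf[i] < maf[j]) i
        else if (maf[j] < maf[i]) j
        else max(i, j)  # MAF tie: drop the later position
      if (is.na(victim)) {  # both protected: mask the pair and move on
        C[min(hit), max(hit)] <- 0; C[max(hit), min(hit)] <- 0
        next
      }
      alive[victim] <- FALSE
      k <- match(victim, sub)
      C[k, ] <- 0; C[, k] <- 0
    }
  }
  ids_all[idx[alive]]
}

#' Apply the full marker QC chain
#'
#' Order of application: MAF filter (markers with undefined or low MAF are
#' removed), Hardy-Weinberg filter, windowed LD pruning.
#'
#' @param geno a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return list with `geno` (the filtered [genotype_matrix()]) and `summary`
#'   (a `data.frame` of marker counts removed per filter).
#' @export
apply_qc <- function(geno, cfg = qc_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m0 <- ncol(geno$dosages)
  maf <- compute_maf(geno)
  keep_maf <- !is.na(maf) & maf >= cfg$maf_min
  g1 <- subset_genotypes(geno, markers = which(keep_maf))
  X <- g1$dosages
  hwe_p <- hwe_test(colSums(X == 0, na.rm = TRUE),
                    colSums(X == 1, na.rm = TRUE),
                    colSums(X == 2, na.rm = TRUE))
  keep_hwe <- hwe_p >= cfg$hwe_p_min
  g2 <- subset_genotypes(g1, markers = which(keep_hwe))
  surv <- ld_prune(g2, cfg)
  g3 <- subset_genotypes(g2, markers = surv)
  summary <- data.frame(
    filter = c("input", "maf", "hwe", "ld_prune", "retained"),
    removed = c(NA, sum(!keep_maf), sum(!keep_hwe),
                ncol(g2$dosages) - length(surv), NA),
    remaining = c(m0, ncol(g1$dosages), ncol(g2$dosages), length(surv),
                  length(surv)))
  list(geno = g3, summary = summary)
}
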