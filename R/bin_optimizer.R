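#' Optimizer configuration
#'
#' Parameters of the bin-based combinatorial marker selection: the strong
#' p-value threshold that defines Subset I, the number of p-value bins and
#' groups per bin, the cross-validation folds used to score a candidate
#' combination, the marker budget (upper subset-size limit, typically from
#' [detect_plateau()]) and the seed controlling fold assignment.
#'
#' @param p_strong p-value threshold below which markers enter Subset I.
#' @param n_bins number of p-value bins `B`.
#' @param n_groups groups per bin `G`.
#' @param cv_folds folds `F` for combination scoring; round-1 work is exactly
#'   `B x G x F` model fits.
#' @param budget marker-count cap (`NULL` until known).
#' @param seed integer seed.
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(p_strong = 0.01, n_bins = 10L, n_groups = 10L,
                             cv_folds = 5L, budget = NULL, seed = 1L) {
  stopifnot(p_strong > 0, p_strong < 1 / n_bins, n_bins >= 1, n_groups >= 1,
            cv_folds >= 1, is.null(budget) || budget > 0)
  structure(list(p_strong = p_strong, n_bins = as.integer(n_bins),
                 n_groups = as.integer(n_groups), cv_folds = as.integer(cv_folds),
                 budget = if (is.null(budget)) NULL else as.integer(budget),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Size of the exhaustive one-group-per-bin search space
#'
#' Closed form `G^B`: the number of combinations that pick one group from
#' every bin, which the chain-wise rolling strategy avoids enumerating (it
#' visits only `B x G` of them).
#'
#' @param n_bins number of bins `B`.
#' @param n_groups groups per bin `G`.
#' @return a double (the count overflows integers quickly).
#' @export
search_space_size <- function(n_bins, n_groups) as.numeric(n_groups)^n_bins

#' Strong-effect marker subset (Subset I)
#'
#' Markers with GWAS `p < p_strong` (strict), in genomic order, then LD
#' pruning to remove redundancy.
#'
#' @param gwas a `gwas_result` from [score_markers()].
#' @param geno the [genotype_matrix()] the scan was run on.
#' @param cfg an [optimizer_config()].
#' @param qc a [qc_config()] providing the pruning parameters.
#' @return character vector of marker ids (possibly empty, with a warning).
#' @export
build_subset1 <- function(gwas, geno, cfg = optimizer_config(), qc = qc_config()) {
  ids <- gwas$marker_id[gwas$p < cfg$p_strong]
  if (!length(ids)) {
    .warnf("no marker reaches p < %g; Subset I is empty", cfg$p_strong)
    return(character(0))
  }
  ld_prune(geno, qc, marker_ids = ids)
}

#' Stratify markers into p-value bins and groups
#'
#' Markers with `p >= p_strong` (and not in Subset I) are assigned to `B`
#' bins tiling `[p_strong, 1]`: the first bin is `[p_strong, 1/B)`, the rest
#' are the equal-width intervals `[1/B, 2/B), ..., [(B-1)/B, 1]` (upper end
#' closed). Each bin is split into `G` equal-width sub-interval groups in
#' ascending p order; with the default `B = G = 10` this yields the 0.01-wide
#' group windows on bins 2-10 and 0.009-wide ones on the narrower first bin.
#' Empty groups are permitted. Markers with `p < p_strong` that were pruned
#' out of Subset I are not re-entered.
#'
#' @param gwas a `gwas_result` covering the candidate pool.
#' @param subset1 marker ids already claimed by Subset I.
#' @param cfg an [optimizer_config()].
#' @return list of class `bin_partition`: `bins` (each with `lo`, `hi` and
#'   `groups`, each group with `lo`, `hi`, `markers` in genomic order),
#'   `n_bins`, `n_groups`, `p_strong` and `marker_universe` (the full marker
#'   ordering used for merges).
#' @export
partition_bins <- function(gwas, subset1, cfg = optimizer_config()) {
  B <- cfg$n_bins; G <- cfg$n_groups
  keep <- gwas$p >= cfg$p_strong & !(gwas$marker_id %in% subset1)
  p <- gwas$p[keep]
  ids <- gwas$marker_id[keep]
  bin_of <- pmin(B, floor(p * B) + 1L)
  bins <- vector("list", B)
  for (b in seq_len(B)) {
    lo <- max(cfg$p_strong, (b - 1) / B); hi <- b / B
    gw <- (hi - lo) / G
    inb <- bin_of == b
    g_of <- pmin(G, floor((p[inb] - lo) / gw) + 1L)
    groups <- vector("list", G)
    for (g in seq_len(G)) {
      groups[[g]] <- list(lo = lo + (g - 1) * gw, hi = lo + g * gw,
                          markers = ids[inb][g_of == g])
    }
    bins[[b]] <- list(lo = lo, hi = hi, groups = groups)
  }
  structure(list(bins = bins, n_bins = B, n_groups = G, p_strong = cfg$p_strong,
                 marker_universe = gwas$marker_id),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  occ <- vapply(x$bins, function(b) sum(lengths(lapply(b$groups, `[[`, "markers"))),
                integer(1L))
  cat(sprintf("bin_partition: %d bins x %d groups over [%g, 1], %d markers\n",
              x$n_bins, x$n_groups, x$p_strong, sum(occ)))
  cat("  bin occupancy:", paste(occ, collapse = " "), "\n")
  invisible(x)
}

#' Chain-wise rolling enumeration of round-1 combinations
#'
#' Bins act as factors and groups as their levels. Starting from all bins at
#' group 1 in bin order, each step moves the current leading bin to the tail
#' of the chain and advances its group index (wrapping `G -> 1`). Exactly
#' `B x G` combinations are produced and every (bin, group) pair leads
#' exactly once. With 5 bins A-E and 4 groups this gives A1-B1-C1-D1-E1, then
#' B1-C1-D1-E1-A2, ..., ending E4-A1-B1-C1-D1.
#'
#' @param cfg an [optimizer_config()], or the number of bins `B` when
#'   `n_groups` is given directly.
#' @param n_groups groups per bin (only when `cfg` is a plain bin count).
#' @return list of `B x G` objects of class `combination`, each with `bins`
#'   (chain order), `groups` (parallel group indices), `leading_bin`,
#'   `leading_group`.
#' @export
enumerate_round1 <- function(cfg, n_groups = NULL) {
  if (is.numeric(cfg)) {
    stopifnot(!is.null(n_groups))
    B <- as.integer(cfg); G <- as.integer(n_groups)
  } else {
    B <- cfg$n_bins; G <- cfg$n_groups
  }
  bins <- seq_len(B)
  groups <- rep(1L, B)
  out <- vector("list", B * G)
  for (k in seq_len(B * G)) {
    out[[k]] <- structure(list(bins = bins, groups = groups,
                               leading_bin = bins[1L], leading_group = groups[1L]),
                          class = "combination")
    lead_b <- bins[1L]; lead_g <- groups[1L]
    bins <- c(bins[-1L], lead_b)
    groups <- c(groups[-1L], if (lead_g == G) 1L else lead_g + 1L)
  }
  out
}

#' @export
format.combination <- function(x, ...) {
  lab <- if (max(x$bins) <= 26L) LETTERS[x$bins] else paste0("b", x$bins)
  paste(paste0(lab, x$groups), collapse = "-")
}

#' @export
print.combination <- function(x, ...) {
  cat("combination:", format(x), "\n")
  invisible(x)
}

## ---- fast neighbour-LD cache -------------------------------------------
## Precomputes r^2 between every marker and its `window - 1` right
## neighbours once, so that the LD pruning inside the optimizer loop reduces
## to index bookkeeping over the (few) pairs exceeding the threshold.
## Markers further apart than the window in the full panel are treated as
## unlinked, which matches the windowed pruning contract.
.ld_cache_build <- function(geno, cfg = qc_config()) {
  X <- .impute_mean(geno$dosages)
  n <- nrow(X); m <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  Xs <- scale(X)
  Xs[, sds == 0] <- 0
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (d in seq_len(min(cfg$ld_window - 1L, m - 1L))) {
    a <- seq_len(m - d)
    r <- colSums(Xs[, a, drop = FALSE] * Xs[, a + d, drop = FALSE]) / (n - 1)
    hit <- which(r^2 > cfg$ld_r2_max)
    pairs_i <- c(pairs_i, hit)
    pairs_j <- c(pairs_j, hit + d)
  }
  ord <- order(pairs_i, pairs_j)
  maf <- compute_maf(X)
  maf[is.na(maf)] <- -1
  list(ids = geno$markers$id, maf = maf,
       pair_i = pairs_i[ord], pair_j = pairs_j[ord])
}

## prune the sorted global index set `idx`; `keep_ids` are protected
.ld_prune_fast <- function(idx, cache, keep_ids = character(0)) {
  m <- length(cache$ids)
  alive <- logical(m)
  alive[idx] <- TRUE
  protected <- logical(m)
  protected[match(keep_ids, cache$ids)] <- TRUE
  pi <- cache$pair_i; pj <- cache$pair_j
  sel <- alive[pi] & alive[pj]
  pi <- pi[sel]; pj <- pj[sel]
  for (k in seq_along(pi)) {
    i <- pi[k]; j <- pj[k]
    if (!alive[i] || !alive[j]) next
    if (protected[i] && protected[j]) next
    victim <-
      if (protected[i]) j
      else if (protected[j]) i
      else if (cache$maf[i] < cache$maf[j]) i
      else if (cache$maf[j] < cache$maf[i]) j
      else max(i, j)
    alive[victim] <- FALSE
  }
  which(alive)
}

#' Score one combination against the accumulated marker set
#'
#' The combination's available markers (its member groups minus any excluded
#' ones) are merged with the accumulated set, LD-pruned (accumulated markers
#' are protected), and the merged set is scored by `cv_folds`-fold
#' cross-validated GBLUP `r^2` on the training samples with a fixed fold
#' assignment.
#'
#' @param comb a `combination`.
#' @param part the `bin_partition`.
#' @param base accumulated marker ids (Subset I plus earlier winners).
#' @param geno training-sample [genotype_matrix()].
#' @param y_train training phenotypes.
#' @param cfg an [optimizer_config()].
#' @param qc a [qc_config()] (pruning parameters); `NULL` skips pruning.
#' @param folds optional fold assignment (defaults to `make_folds` from
#'   `cfg$seed`).
#' @param excluded optional `B x G` logical matrix of retired groups.
#' @param ld_cache optional cache from the internal neighbour-LD index (used
#'   by [run_optimization()] to avoid re-scanning windows).
#' @param score_fn optional replacement scorer `function(merged, base)`
#'   returning a numeric accuracy; used for structural tests.
#' @return list with `accuracy` and `merged` (the pruned merged id vector).
#' @export
score_combination <- function(comb, part, base, geno, y_train,
                              cfg = optimizer_config(), qc = qc_config(),
                              folds = NULL, excluded = NULL, ld_cache = NULL,
                              score_fn = NULL) {
  avail <- character(0)
  for (k in seq_along(comb$bins)) {
    b <- comb$bins[k]; g <- comb$groups[k]
    if (!is.null(excluded) && excluded[b, g]) next
    avail <- c(avail, part$bins[[b]]$groups[[g]]$markers)
  }
  uni <- part$marker_universe
  merged <- uni[uni %in% union(base, avail)]
  if (!is.null(qc) && length(merged) > 1L) {
    if (!is.null(ld_cache)) {
      merged <- ld_cache$ids[.ld_prune_fast(match(merged, ld_cache$ids),
                                            ld_cache, keep_ids = base)]
    } else {
      merged <- ld_prune(geno, qc, marker_ids = merged, keep = base)
    }
  }
  if (!is.null(score_fn)) return(list(accuracy = score_fn(merged, base), merged = merged))
  if (!length(merged)) {
    message("score_combination: empty merged set, accuracy 0")
    return(list(accuracy = 0, merged = merged))
  }
  if (is.null(folds)) folds <- make_folds(length(y_train), cfg$cv_folds, seed = cfg$seed)
  G <- build_grm(geno$dosages[, merged, drop = FALSE])
  list(accuracy = .cv_gblup_r2(G, y_train, folds), merged = merged)
}

#' Run the chain-wise rolling bin optimization
#'
#' Round 1 scores the full `B x G` enumeration, each combination merged with
#' Subset I. The winning combination's merged set becomes the accumulated
#' set, its leading group is retired from its bin and from every surviving
#' combination, and the remaining combinations proceed to the next round,
#' now merged with the full accumulated set (full-bin coverage is no longer
#' required). The loop stops once the accumulated set reaches the budget or
#' the candidates are exhausted. Ties on accuracy go to the earliest
#' combination in enumeration order; given the seed the procedure is fully
#' deterministic. The fold assignment is redrawn per round (from
#' `cfg$seed + round`) but shared by all combinations within the round.
#'
#' @param part a `bin_partition`.
#' @param subset1 Subset I marker ids.
#' @param geno training-sample [genotype_matrix()].
#' @param y_train training phenotypes.
#' @param cfg an [optimizer_config()] with a non-`NULL` `budget`.
#' @param qc a [qc_config()]; `NULL` disables merge-time pruning.
#' @param score_fn optional scorer override (see [score_combination()]).
#' @param verbose print per-round progress.
#' @return list of class `selection_report`: `subset1`, `subset2`, `final`,
#'   `rounds` (audit table with round, leading group, candidate count,
#'   winning accuracy, markers added, cumulative size) and `budget`.
#' @export
run_optimization <- function(part, subset1, geno, y_train, cfg,
                             qc = qc_config(), score_fn = NULL, verbose = FALSE) {
  if (is.null(cfg$budget)) .stopf("cfg$budget must be set (see detect_plateau)")
  if (cfg$budget < length(subset1))
    .warnf("budget %d is below |Subset I| = %d; returning Subset I unchanged",
           cfg$budget, length(subset1))
  ld_cache <- NULL
  if (is.null(score_fn) && !is.null(qc) && !is.null(geno))
    ld_cache <- .ld_cache_build(geno, qc)
  combos <- enumerate_round1(cfg)
  excluded <- matrix(FALSE, part$n_bins, part$n_groups)
  acc_set <- subset1
  rounds <- list()
  r <- 0L
  while (length(acc_set) < cfg$budget && length(combos) > 0L) {
    r <- r + 1L
    folds <- if (is.null(score_fn))
      make_folds(length(y_train), cfg$cv_folds, seed = cfg$seed + r) else NULL
    scored <- lapply(combos, score_combination, part = part, base = acc_set,
                     geno = geno, y_train = y_train, cfg = cfg, qc = qc,
                     folds = folds, excluded = excluded, ld_cache = ld_cache,
                     score_fn = score_fn)
    accs <- vapply(scored, `[[`, 0, "accuracy")
    win <- which.max(accs)  # earliest max: deterministic tie-break
    added <- length(scored[[win]]$merged) - length(acc_set)
    acc_set <- scored[[win]]$merged
    wb <- combos[[win]]$leading_bin; wg <- combos[[win]]$leading_group
    rounds[[r]] <- data.frame(round = r, lead_bin = wb, lead_group = wg,
                              n_candidates = length(combos),
                              accuracy = accs[win], n_added = added,
                              cumulative = length(acc_set))
    if (verbose)
      message(sprintf("round %d: %s wins (acc %.4f), +%d markers, cumulative %d",
                      r, format(combos[[win]]), accs[win], added, length(acc_set)))
    excluded[wb, wg] <- TRUE
    combos <- combos[-win]
  }
  rounds <- if (length(rounds)) do.call(rbind, rounds)
            else data.frame(round = integer(0), lead_bin = integer(0),
                            lead_group = integer(0), n_candidates = integer(0),
                            accuracy = numeric(0), n_added = integer(0),
                            cumulative = integer(0))
  structure(list(subset1 = subset1, subset2 = setdiff(acc_set, subset1),
                 final = acc_set, rounds = rounds, budget = cfg$budget),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report: |Subset I| = %d, |Subset II| = %d, |final| = %d (budget %d, %d rounds)\n",
              length(x$subset1), length(x$subset2), length(x$final),
              x$budget, nrow(x$rounds)))
  invisible(x)
}

#' Split a selection into Subset I and its complement
#'
#' Subset II is every selected marker not in Subset I; the two are disjoint
#' by construction.
#'
#' @param report a `selection_report` from [run_optimization()].
#' @return list with `subset1` and `subset2`.
#' @export
split_subset2 <- function(report) {
  stopifnot(inherits(report, "selection_report"))
  s2 <- setdiff(report$final, report$subset1)
  stopifnot(!length(intersect(report$subset1, s2)))
  list(subset1 = report$subset1, subset2 = s2)
}
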