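#' Evaluation configuration
#'
#' Replicated hold-out design: per replicate the population is split into
#' training (`train_frac`) and testing sets; marker selection runs on the
#' training partition only and all compared marker sets share the same
#' splits.
#'
#' @param train_frac training fraction (default 0.75).
#' @param n_replicates number of independent splits (default 15).
#' @param n_random_subsets random equal-size subsets for the baseline
#'   (default 500).
#' @param alpha significance level for the paired tests.
#' @param seed integer seed.
#' @return list of class `eval_config`.
#' @export
eval_config <- function(train_frac = 0.75, n_replicates = 15L,
                        n_random_subsets = 500L, alpha = 0.05, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, n_replicates >= 2,
            n_random_subsets >= 1, alpha > 0, alpha < 1)
  structure(list(train_frac = train_frac, n_replicates = as.integer(n_replicates),
                 n_random_subsets = as.integer(n_random_subsets),
                 alpha = alpha, seed = as.integer(seed)),
            class = "eval_config")
}

#' Replicated train/test splits
#'
#' Disjoint exhaustive splits at `train_frac`, one pair per replicate,
#' deterministic given the seed.
#'
#' @param sample_ids sample identifiers (or anything of length `n`).
#' @param cfg an [eval_config()].
#' @return list of `n_replicates` lists with integer `train` and `test`
#'   index vectors.
#' @export
make_splits <- function(sample_ids, cfg = eval_config()) {
  n <- length(sample_ids)
  if (n < 8L) .stopf("need at least 8 samples to split, got %d", n)
  n_train <- round(cfg$train_frac * n)
  if (n_train < 1L || n_train >= n) .stopf("train fraction leaves an empty partition")
  withr::with_seed(cfg$seed, lapply(seq_len(cfg$n_replicates), function(r) {
    tr <- sort(sample(n, n_train))
    list(train = tr, test = setdiff(seq_len(n), tr))
  }))
}

#' Prediction accuracy as squared correlation
#'
#' Squared Pearson correlation between observed and predicted phenotypes
#' (the genomic-selection convention for the coefficient of determination).
#' A constant prediction scores 0 rather than erroring. `method = "rss"`
#' gives the regression-residual form `1 - SSE/SST` instead.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @param method `"cor2"` (default) or `"rss"`.
#' @return a fraction (non-negative for `"cor2"`).
#' @export
accuracy_r2 <- function(observed, predicted, method = c("cor2", "rss")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted)) .stopf("length mismatch")
  if (length(observed) < 3L) .stopf("need at least 3 pairs")
  if (stats::sd(observed) == 0) .stopf("observed values are constant")
  if (method == "rss")
    return(1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2))
  if (stats::sd(predicted) == 0) {
    message("accuracy_r2: constant prediction, returning 0")
    return(0)
  }
  stats::cor(observed, predicted)^2
}

#' Mean accuracy of random equal-size marker subsets
#'
#' Holds one train/test split fixed and averages the GBLUP test `r^2` over
#' `n_subsets` uniform draws of `size` markers from the pool.
#'
#' @param pool marker ids to draw from.
#' @param size subset size.
#' @param n_subsets number of random subsets.
#' @param geno a [genotype_matrix()] over all samples.
#' @param y phenotype vector over all samples.
#' @param split list with `train` and `test` index vectors.
#' @param seed integer seed.
#' @return mean test `r^2` (attribute `accs` carries the per-subset values).
#' @export
random_subset_baseline <- function(pool, size, n_subsets, geno, y, split,
                                   seed = 1L) {
  if (size > length(pool)) .stopf("size %d exceeds pool %d", size, length(pool))
  accs <- withr::with_seed(seed, vapply(seq_len(n_subsets), function(s) {
    ids <- if (size == length(pool)) pool else sample(pool, size)
    G <- build_grm(geno$dosages[, ids, drop = FALSE])
    pred <- gblup_fit_predict(y[split$train], G, split$train, split$test)
    accuracy_r2(y[split$test], pred)
  }, numeric(1L)))
  structure(mean(accs), accs = accs)
}

#' One-tailed paired t-test for accuracy gains
#'
#' Tests `H1: mean(x - y) > 0` for per-replicate accuracies paired by split.
#' When the differences have zero variance the p-value is 0, 1 or 0.5 for a
#' positive, negative or zero mean difference (degenerate-case convention).
#'
#' @param x per-replicate accuracies of the method.
#' @param y per-replicate accuracies of the baseline, same splits.
#' @return p-value.
#' @export
paired_onetailed_t <- function(x, y) {
  if (length(x) != length(y)) .stopf("length mismatch")
  if (length(x) < 3L) .stopf("need at least 3 paired replicates")
  d <- x - y
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d))))
    return(if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  stats::t.test(x, y, paired = TRUE, alternative = "greater")$p.value
}

#' Marker selection within one training partition
#'
#' The per-replicate core of the pipeline: principal components and kinship
#' from the training genotypes, mixed-model scan over the pool, Subset I,
#' bin partition, and the rolling optimization - touching only
#' `y[split$train]`. Permuting the test phenotypes cannot change the result.
#'
#' @param geno QC-filtered [genotype_matrix()] over all samples.
#' @param y phenotype vector over all samples.
#' @param split list with `train` and `test` index vectors.
#' @param pool candidate marker ids (the GO pool).
#' @param opt an [optimizer_config()] with `budget` set.
#' @param qc a [qc_config()].
#' @param n_pcs number of genotype principal components used as GWAS
#'   covariates.
#' @return a `selection_report` (see [run_optimization()]) with the GWAS
#'   table attached as attribute `gwas`.
#' @export
select_markers_for_split <- function(geno, y, split, pool, opt,
                                     qc = qc_config(), n_pcs = 3L) {
  g_tr <- subset_genotypes(geno, samples = split$train)
  y_tr <- y[split$train]
  pcs <- pca_covariates(g_tr, k = n_pcs)
  K <- build_grm(g_tr)
  null_fit <- fit_null_lmm(y_tr, K, X = pcs)
  gwas <- score_markers(g_tr, null_fit, marker_scope = pool)
  s1 <- suppressWarnings(build_subset1(gwas, g_tr, opt, qc))
  part <- partition_bins(gwas, s1, opt)
  rep_out <- run_optimization(part, s1, g_tr, y_tr, opt, qc)
  attr(rep_out, "gwas") <- gwas
  rep_out
}

## test-set r^2 of one marker set under one split (GRM over all samples,
## phenotypes of the test partition never seen before prediction)
.eval_marker_set <- function(ids, geno, y, split) {
  if (length(ids) < 2L) return(NA_real_)
  G <- build_grm(geno$dosages[, ids, drop = FALSE])
  pred <- gblup_fit_predict(y[split$train], G, split$train, split$test)
  accuracy_r2(y[split$test], pred)
}

#' Run the full selection-and-evaluation pipeline
#'
#' Orchestrates: marker QC, GO pool construction, replicated train/test
#' splits, per-replicate selection (GWAS, Subset I, bins, rolling
#' optimization) and evaluation of the final subset against the full marker
#' set, equal-size random subsets, Subset I and Subset II, with one-tailed
#' paired t-tests on the per-replicate accuracies.
#'
#' The marker budget is taken from `config$budget` when numeric; when
#' `"auto"` it is estimated once by [sample_accuracy_curve()] +
#' [detect_plateau()] on the first replicate's training partition and reused
#' across replicates (the desk-scale fast mode; set
#' `config$budget_per_replicate = TRUE` to re-estimate each time).
#'
#' @param config a named list (or path to a JSON file with the same fields):
#'   `geno` (a [genotype_matrix()] or a path + `geno_format`), `pheno` (a
#'   phenotype table or path), `trait` (trait column name), `genes` (gene
#'   models or path + `gene_format`), `go` (GO map or path), and optionally
#'   `qc`, `opt`, `eval`, `plateau` (config objects or argument lists),
#'   `min_snps` (effective-term threshold, default 200), `flank_bp`,
#'   `n_pcs`, `budget` (`"auto"` or integer), `budget_grid`, `budget_reps`,
#'   `skip_qc` (when the input is already filtered), `out_dir` (write TSV
#'   artifacts there when set).
#' @return list of class `bingogs_result`: `comparison` (replicate x marker
#'   set accuracy table), `ttests`, `reports` (per-replicate
#'   `selection_report`s), `pool`, `budget`, `qc_summary`, `splits`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg_obj <- function(x, ctor) {
    if (inherits(x, c("qc_config", "optimizer_config", "eval_config",
                      "plateau_config"))) x
    else do.call(ctor, as.list(x %||% list()))
  }
  qc <- cfg_obj(config$qc, qc_config)
  opt <- cfg_obj(config$opt, optimizer_config)
  ev <- cfg_obj(config$eval, eval_config)
  plat <- cfg_obj(config$plateau, plateau_config)

  geno <- config$geno
  if (is.character(geno))
    geno <- read_genotypes(geno, format = config$geno_format %||% "vcf")
  pheno <- config$pheno
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  trait <- config$trait %||% setdiff(names(pheno), "sample_id")[1L]
  genes <- config$genes
  if (is.character(genes))
    genes <- read_gene_models(genes, format = config$gene_format %||% "gff3")
  go <- config$go
  if (is.character(go)) go <- read_go_map(go)

  ## align samples, drop per-trait missing phenotypes
  keep <- match(pheno$sample_id, geno$sample_ids)
  if (anyNA(keep)) .stopf("pipeline: %d phenotype sample(s) missing from genotypes", sum(is.na(keep)))
  ok <- !is.na(pheno[[trait]])
  geno <- subset_genotypes(geno, samples = keep[ok])
  y <- pheno[[trait]][ok]

  qc_summary <- NULL
  if (!isTRUE(config$skip_qc)) {
    qcres <- tryCatch(apply_qc(geno, qc),
                      error = function(e) .stopf("pipeline stage 'qc' failed: %s", conditionMessage(e)))
    geno <- qcres$geno
    qc_summary <- qcres$summary
  }

  idx <- tryCatch({
    i <- map_terms_to_markers(go, genes, geno, flank_bp = config$flank_bp %||% 0L)
    select_effective_terms(i, min_snps = config$min_snps %||% 200L,
                           include_terms = config$include_terms,
                           exclude_terms = config$exclude_terms)
  }, error = function(e) .stopf("pipeline stage 'go_pool' failed: %s", conditionMessage(e)))
  pool <- build_go_pool(idx)
  if (!length(pool)) .stopf("pipeline stage 'go_pool': empty GO marker pool")

  splits <- make_splits(geno$sample_ids, ev)

  budget_spec <- config$budget %||% "auto"
  budget <- if (is.numeric(budget_spec)) as.integer(budget_spec) else NULL
  per_rep_budget <- isTRUE(config$budget_per_replicate)
  estimate_budget <- function(split) {
    g_tr <- subset_genotypes(geno, samples = split$train)
    curve <- sample_accuracy_curve(pool, g_tr, y[split$train],
                                   grid = config$budget_grid %||% "auto",
                                   n_reps = config$budget_reps %||% 50L,
                                   cv_folds = opt$cv_folds, seed = ev$seed)
    as.integer(detect_plateau(curve, plat))
  }

  sets <- c("full", "random", "subset1", "subset2", "final")
  comparison <- matrix(NA_real_, ev$n_replicates, length(sets),
                       dimnames = list(NULL, sets))
  reports <- vector("list", ev$n_replicates)
  for (r in seq_len(ev$n_replicates)) {
    split <- splits[[r]]
    b <- if (!is.null(budget) && !per_rep_budget) budget else estimate_budget(split)
    if (r == 1L && is.null(budget)) budget <- b
    opt_r <- opt; opt_r$budget <- b; opt_r$seed <- opt$seed + r * 1000L
    rep_out <- tryCatch(
      select_markers_for_split(geno, y, split, pool, opt_r, qc,
                               n_pcs = config$n_pcs %||% 3L),
      error = function(e) .stopf("pipeline stage 'selection' (replicate %d) failed: %s",
                                 r, conditionMessage(e)))
    reports[[r]] <- rep_out
    comparison[r, "full"] <- .eval_marker_set(geno$markers$id, geno, y, split)
    comparison[r, "subset1"] <- .eval_marker_set(rep_out$subset1, geno, y, split)
    comparison[r, "subset2"] <- .eval_marker_set(rep_out$subset2, geno, y, split)
    comparison[r, "final"] <- .eval_marker_set(rep_out$final, geno, y, split)
    comparison[r, "random"] <- random_subset_baseline(
      geno$markers$id, min(length(rep_out$final), ncol(geno$dosages)),
      ev$n_random_subsets, geno, y, split, seed = ev$seed + r)
  }
  comparison <- as.data.frame(cbind(replicate = seq_len(ev$n_replicates), comparison))
  pair <- function(a, b) {
    ok <- stats::complete.cases(comparison[, c(a, b)])
    if (sum(ok) >= 3L) paired_onetailed_t(comparison[[a]][ok], comparison[[b]][ok]) else NA_real_
  }
  ttests <- data.frame(
    comparison = c("final_vs_full", "final_vs_random", "final_vs_subset1",
                   "subset2_vs_subset1"),
    p_value = c(pair("final", "full"), pair("final", "random"),
                pair("final", "subset1"), pair("subset2", "subset1")))
  out <- structure(list(comparison = comparison, ttests = ttests,
                        reports = reports, pool = pool, budget = budget,
                        trait = trait, qc_summary = qc_summary, splits = splits,
                        config = list(qc = qc, opt = opt, eval = ev, plateau = plat)),
                   class = "bingogs_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(comparison, file.path(config$out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ttests, file.path(config$out_dir, "ttests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (r in seq_along(reports)) {
      write_marker_subset(reports[[r]]$final,
                          file.path(config$out_dir, sprintf("final_rep%02d.txt", r)))
    }
  }
  out
}

#' @export
print.bingogs_result <- function(x, ...) {
  cat(sprintf("bingogs_result: trait '%s', %d replicates, budget %d, pool %d markers\n",
              x$trait, nrow(x$comparison), x$budget, length(x$pool)))
  mu <- colMeans(x$comparison[, -1L, drop = FALSE], na.rm = TRUE)
  cat("mean test r2 by marker set:\n")
  print(round(mu, 4))
  cat("one-tailed paired t-tests:\n")
  print(transform(x$ttests, p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}
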