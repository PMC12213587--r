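## fake GWAS table with prescribed p-values, universe m0001..m{n}
.fake_gwas <- function(p) {
  structure(data.frame(marker_id = sprintf("m%04d", seq_along(p)),
                       chrom = "1", pos = seq_along(p), beta = 0, se = 1, p = p,
                       stringsAsFactors = FALSE),
            class = c("gwas_result", "data.frame"))
}

test_that("search_space_size: closed form G^B against brute-force enumeration", {
  expect_equal(search_space_size(3, 4), nrow(expand.grid(1:4, 1:4, 1:4)))
  expect_equal(search_space_size(2, 5), 25)
  expect_equal(search_space_size(10, 10), 1e10)
})

test_that("subset I uses strict p < threshold and prunes", {
  gw <- .fake_gwas(c(0.001, 0.01, 0.5, 0.009, 0.2))
  d <- fx_small()
  g5 <- subset_genotypes(d$geno, markers = 1:5)
  g5$markers$id <- sprintf("m%04d", 1:5)
  colnames(g5$dosages) <- g5$markers$id
  s1 <- build_subset1(gw, g5, optimizer_config())
  expect_setequal(s1, c("m0001", "m0004"))  # p == 0.01 excluded
  expect_warning(s0 <- build_subset1(.fake_gwas(rep(0.5, 5)), g5,
                                     optimizer_config()), "empty")
  expect_length(s0, 0L)
})

test_that("partition_bins tiles [p_strong, 1] with disjoint ascending groups", {
  p <- c(0.005, 0.01, 0.099, 0.15, 0.2, 0.55, 0.9999, 1.0)
  gw <- .fake_gwas(p)
  part <- partition_bins(gw, subset1 = "m0001", optimizer_config())
  expect_s3_class(part, "bin_partition")
  memb <- function(id) {
    for (b in seq_len(part$n_bins)) for (g in seq_len(part$n_groups))
      if (id %in% part$bins[[b]]$groups[[g]]$markers) return(c(b, g))
    c(NA, NA)
  }
  expect_true(all(is.na(memb("m0001"))))      # subset-1 marker excluded
  expect_equal(memb("m0002")[1], 1)           # p = p_strong enters bin 1
  expect_equal(memb("m0003")[1], 1)           # 0.099 in [0.01, 0.1)
  expect_equal(memb("m0004")[1], 2)           # 0.15 in [0.1, 0.2)
  expect_equal(memb("m0005")[1], 3)           # left-closed: 0.2 -> [0.2, 0.3)
  expect_equal(memb("m0008"), c(10, 10))      # p = 1 closes the last group
  ## interval geometry: bins tile [0.01, 1], groups tile their bin
  lo <- vapply(part$bins, `[[`, 0, "lo"); hi <- vapply(part$bins, `[[`, 0, "hi")
  expect_equal(lo, c(0.01, seq(0.1, 0.9, 0.1)))
  expect_equal(hi, seq(0.1, 1, 0.1))
  g1w <- diff(unlist(lapply(part$bins[[1]]$groups, `[[`, "lo")))
  expect_equal(g1w, rep(0.009, 9), tolerance = 1e-12)
  g2w <- diff(unlist(lapply(part$bins[[2]]$groups, `[[`, "lo")))
  expect_equal(g2w, rep(0.01, 9), tolerance = 1e-12)
  ## all markers with p >= p_strong assigned exactly once
  all_assigned <- unlist(lapply(part$bins, function(b)
    lapply(b$groups, `[[`, "markers")))
  expect_identical(sort(all_assigned), sort(gw$marker_id[p >= 0.01]))
  expect_false(anyDuplicated(all_assigned) > 0)
})

test_that("bin occupancy of uniform p-values matches the multinomial oracle", {
  withr::with_seed(13, {
    p <- runif(10000)
    part <- partition_bins(.fake_gwas(p), character(0), optimizer_config())
    occ <- vapply(part$bins, function(b) sum(lengths(lapply(b$groups, `[[`, "markers"))),
                  integer(1))
    width <- c(0.09, rep(0.1, 9))
    expected <- sum(p >= 0.01) * width / 0.99
    expect_true(all(abs(occ - expected) < 3 * sqrt(expected)))
  })
})

test_that("chain-wise rolling enumeration matches its closed-form oracle", {
  for (B in c(1, 2, 4, 6)) for (G in c(1, 3, 6)) {
    combos <- enumerate_round1(B, G)
    oracle <- rolling_oracle(B, G)
    expect_length(combos, B * G)
    for (k in seq_along(combos)) {
      expect_equal(combos[[k]]$bins, oracle[[k]]$bins)
      expect_equal(combos[[k]]$groups, oracle[[k]]$groups)
    }
    leads <- t(vapply(combos, function(cb) c(cb$leading_bin, cb$leading_group),
                      integer(2)))
    expect_equal(nrow(unique(leads)), B * G)  # every (bin, group) leads once
  }
  expect_equal(format(enumerate_round1(1, 1)[[1]]), "A1")
})

test_that("score_combination: no-op merge and prune idempotence", {
  d <- fx_small()
  tr <- 1:100
  g_tr <- subset_genotypes(d$geno, samples = tr)
  y_tr <- d$pheno$y[tr]
  nf <- fit_null_lmm(y_tr, build_grm(g_tr), X = pca_covariates(g_tr, 2))
  gw <- score_markers(g_tr, nf)
  opt <- optimizer_config(n_bins = 4, n_groups = 3, cv_folds = 3, budget = 200,
                          seed = 3)
  s1 <- suppressWarnings(build_subset1(gw, g_tr, opt))
  part <- partition_bins(gw, s1, opt)
  folds <- make_folds(length(y_tr), 3, seed = 1)
  comb <- enumerate_round1(opt)[[1]]
  excl_all <- matrix(TRUE, 4, 3)
  base_score <- score_combination(comb, part, s1, g_tr, y_tr, opt,
                                  folds = folds, excluded = excl_all)
  expect_identical(base_score$merged, s1)   # all groups excluded: no-op
  full <- score_combination(comb, part, s1, g_tr, y_tr, opt, folds = folds)
  again <- score_combination(comb, part, full$merged, g_tr, y_tr, opt,
                             folds = folds)
  expect_identical(sort(again$merged), sort(full$merged))  # prune idempotent
  expect_equal(again$accuracy, full$accuracy)
})

test_that("run_optimization structure: rounds, exclusion, budget, determinism", {
  withr::with_seed(17, {
    p <- runif(600, 0.01, 1)
    gw <- .fake_gwas(p)
    opt <- optimizer_config(n_bins = 3, n_groups = 3, cv_folds = 2,
                            budget = 250, seed = 5)
    part <- partition_bins(gw, character(0), opt)
    ## stub scorer: prefer larger merged sets, deterministic
    stub <- function(merged, base) length(merged) / 1000
    rep1 <- run_optimization(part, character(0), geno = NULL, y_train = NULL,
                             cfg = opt, qc = NULL, score_fn = stub)
    expect_s3_class(rep1, "selection_report")
    expect_true(all(diff(rep1$rounds$cumulative) >= 0))
    expect_equal(rep1$rounds$n_candidates, 9:(10 - nrow(rep1$rounds)))
    expect_gte(length(rep1$final), opt$budget)
    ## winner's leading group never wins twice
    expect_false(anyDuplicated(rep1$rounds[, c("lead_bin", "lead_group")]) > 0)
    ## determinism
    rep2 <- run_optimization(part, character(0), NULL, NULL, opt, qc = NULL,
                             score_fn = stub)
    expect_identical(rep1$final, rep2$final)
    expect_identical(rep1$rounds, rep2$rounds)
    ## saturated budget: zero rounds
    opt0 <- optimizer_config(n_bins = 3, n_groups = 3, budget = 5, seed = 5)
    s1 <- sprintf("q%02d", 1:5)
    part0 <- partition_bins(gw, s1, opt0)
    r0 <- run_optimization(part0, s1, NULL, NULL, opt0, qc = NULL, score_fn = stub)
    expect_equal(nrow(r0$rounds), 0L)
    expect_identical(r0$final, s1)
  })
})

test_that("adding a QTN-tagging group beats the no-op merge in most seeds", {
  d <- fx_small()
  wins <- 0L; tries <- 0L
  for (s in 1:10) {
    tr <- withr::with_seed(s, sample(150, 100))
    g_tr <- subset_genotypes(d$geno, samples = tr)
    y_tr <- d$pheno$y[tr]
    nf <- fit_null_lmm(y_tr, build_grm(g_tr), X = pca_covariates(g_tr, 2))
    gw <- score_markers(g_tr, nf)
    opt <- optimizer_config(n_bins = 5, n_groups = 5, cv_folds = 5,
                            budget = 500, seed = s)
    s1 <- suppressWarnings(build_subset1(gw, g_tr, opt))
    part <- partition_bins(gw, s1, opt)
    ## first group (by ascending p) holding a marker in LD > 0.5 with a QTN
    Xi <- g_tr$dosages
    tagged <- NULL
    for (b in seq_len(5)) {
      for (g in seq_len(5)) {
        mks <- part$bins[[b]]$groups[[g]]$markers
        if (!length(mks)) next
        r2q <- vapply(mks, function(m) {
          max(vapply(intersect(d$qtn$marker_id, colnames(Xi)), function(q)
            ld_r2(Xi[, m], Xi[, q]), 0), 0)
        }, 0)
        if (any(r2q > 0.5)) { tagged <- c(b, g); break }
      }
      if (!is.null(tagged)) break
    }
    if (is.null(tagged)) next
    tries <- tries + 1L
    comb <- structure(list(bins = tagged[1], groups = tagged[2],
                           leading_bin = tagged[1], leading_group = tagged[2]),
                      class = "combination")
    folds <- make_folds(length(y_tr), 5, seed = s)
    with_grp <- score_combination(comb, part, s1, g_tr, y_tr, opt, folds = folds)
    no_op <- score_combination(comb, part, s1, g_tr, y_tr, opt, folds = folds,
                               excluded = matrix(TRUE, 5, 5))
    if (with_grp$accuracy > no_op$accuracy) wins <- wins + 1L
  }
  expect_gte(tries, 5L)
  expect_gte(wins / tries, 0.8)
})

test_that("split_subset2 is the exact set difference and disjoint", {
  rep0 <- structure(list(subset1 = c("a", "b"), subset2 = c("c"),
                         final = c("a", "b", "c"),
                         rounds = data.frame(), budget = 3L),
                    class = "selection_report")
  sp <- split_subset2(rep0)
  expect_equal(sp$subset2, "c")
  expect_length(intersect(sp$subset1, sp$subset2), 0L)
  rep0$final <- c("a", "b")
  expect_length(split_subset2(rep0)$subset2, 0L)
  expect_equal(length(rep0$final), length(sp$subset1) + 0L)
})
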