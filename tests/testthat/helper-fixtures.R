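## Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (!exists(name, envir = .fx_cache)) assign(name, maker(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

## small dataset used by most module tests
fx_small <- function() fx("small", function() {
  simulate_dataset(sim_config(n_samples = 150, n_markers = 1200, n_chrom = 3,
                              n_genes = 30, n_terms = 8, qtn_count = 20,
                              h2 = 0.7, seed = 42))
})

## GBLUP test r^2 of a marker set under a split, via exported functions only
eval_set <- function(ids, geno, y, split) {
  G <- build_grm(geno$dosages[, ids, drop = FALSE])
  pred <- gblup_fit_predict(y[split$train], G, split$train, split$test)
  accuracy_r2(y[split$test], pred)
}

## brute-force re-check of the windowed-pruning post-condition: no surviving
## pair that shared a window may exceed the r^2 threshold
check_prune_postcondition <- function(geno, surviving, cfg) {
  ids <- geno$markers$id
  X <- geno$dosages
  alive <- ids %in% surviving
  m <- length(ids)
  starts <- seq(1L, max(1L, m - 1L), by = cfg$ld_step)
  for (s in starts) {
    e <- min(s + cfg$ld_window - 1L, m)
    sub <- which(alive[s:e]) + s - 1L
    if (length(sub) < 2L) next
    for (a in seq_along(sub)[-length(sub)]) for (b in (a + 1L):length(sub)) {
      r2 <- ld_r2(X[, sub[a]], X[, sub[b]])
      if (!is.na(r2) && r2 > cfg$ld_r2_max) return(FALSE)
    }
  }
  TRUE
}

## closed-form oracle for the chain-wise rolling enumeration: combination k's
## chain starts at bin ((k-1) mod B)+1; bin b's group index is one plus the
## number of times b has already led (combinations b, b+B, b+2B, ... < k),
## wrapped at G
rolling_oracle <- function(B, G) {
  B <- as.integer(B); G <- as.integer(G)
  lapply(seq_len(B * G), function(k) {
    lead <- (k - 1L) %% B + 1L
    bins <- ((seq_len(B) + lead - 2L) %% B) + 1L
    groups <- vapply(bins, function(b) {
      n_led <- if (k - 1L >= b) (k - 1L - b) %/% B + 1L else 0L
      n_led %% G + 1L
    }, integer(1L))
    list(bins = bins, groups = groups)
  })
}
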