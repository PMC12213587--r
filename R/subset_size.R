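#' Plateau-detection configuration for the marker-budget curve
#'
#' @param ma_window moving-average window (3 or 5, trailing).
#' @param near_zero_eps "near zero" tolerance for the slope, as a fraction of
#'   the maximum observed slope. `NA` disables the near-zero rule.
#' @param run_length number of consecutive near-zero intervals required.
#' @param drop_frac relative slope drop triggering a plateau (a slope below
#'   `(1 - drop_frac)` times the prior-average slope). `NA` disables the
#'   drop rule.
#' @param drop_ref reference for the prior average: `"all"` (running mean of
#'   every earlier slope, the default) or `"window"` (mean of the previous
#'   `ma_window` slopes only).
#' @return list of class `plateau_config`.
#' @export
plateau_config <- function(ma_window = 3L, near_zero_eps = 0.1,
                           run_length = 3L, drop_frac = 0.2,
                           drop_ref = c("all", "window")) {
  stopifnot(ma_window %in% c(3L, 5L), run_length >= 1,
            is.na(near_zero_eps) || (near_zero_eps > 0 && near_zero_eps < 1),
            is.na(drop_frac) || (drop_frac > 0 && drop_frac < 1))
  structure(list(ma_window = as.integer(ma_window),
                 near_zero_eps = near_zero_eps,
                 run_length = as.integer(run_length),
                 drop_frac = drop_frac,
                 drop_ref = match.arg(drop_ref)),
            class = "plateau_config")
}

#' Monte Carlo size-accuracy curve
#'
#' For each candidate subset size, draws `n_reps` uniform random marker
#' subsets (without replacement) from the pool and records the mean and
#' standard deviation of the cross-validated GBLUP `r^2` on the training
#' samples. Reproducible given `seed`.
#'
#' @param pool marker-id pool to sample from.
#' @param geno a [genotype_matrix()] restricted to training samples.
#' @param y training phenotypes (same order as `geno` samples).
#' @param grid increasing integer vector of subset sizes; `"auto"` spaces 15
#'   sizes between 2 and 50 percent of the pool.
#' @param n_reps random draws per size (default 50).
#' @param cv_folds folds for the internal cross-validation.
#' @param seed integer seed.
#' @return `data.frame` of class `accuracy_curve` with columns `size`,
#'   `mean_acc`, `sd_acc`; attribute `n_reps`.
#' @export
sample_accuracy_curve <- function(pool, geno, y, grid = "auto", n_reps = 50L,
                                  cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  P <- length(pool)
  if (identical(grid, "auto"))
    grid <- unique(pmax(round(seq(0.02 * P, 0.5 * P, length.out = 15L)), cv_folds))
  grid <- sort(as.integer(grid))
  if (any(grid > P)) .stopf("grid size %d exceeds pool size %d", max(grid), P)
  folds <- make_folds(length(y), cv_folds, seed = seed)
  res <- withr::with_seed(seed, {
    lapply(grid, function(sz) {
      accs <- vapply(seq_len(n_reps), function(r) {
        ids <- if (sz == P) pool else sample(pool, sz)
        G <- build_grm(geno$dosages[, ids, drop = FALSE])
        .cv_gblup_r2(G, y, folds)
      }, numeric(1L))
      c(mean(accs), stats::sd(accs))
    })
  })
  out <- data.frame(size = grid,
                    mean_acc = vapply(res, `[`, 0, 1L),
                    sd_acc = vapply(res, `[`, 0, 2L))
  attr(out, "n_reps") <- n_reps
  class(out) <- c("accuracy_curve", "data.frame")
  out
}

#' Trailing moving average
#'
#' `MA_t = mean(y[(t - window + 1):t])`, defined for `t >= window`; earlier
#' positions are `NA` so the output aligns with the input.
#'
#' @param y numeric series.
#' @param window window length (`>= 1`).
#' @return numeric vector of the same length as `y`.
#' @export
moving_average <- function(y, window) {
  window <- as.integer(window)
  if (window < 1L) .stopf("window must be >= 1")
  if (length(y) < window) .stopf("series shorter than window")
  out <- stats::filter(y, rep(1 / window, window), sides = 1)
  as.numeric(out)
}

#' First difference of a smoothed series
#'
#' `Slope_t = MA_t - MA_{t-1}`; the first defined entry follows the first
#' two defined entries of `ma`.
#'
#' @param ma numeric series (typically from [moving_average()]).
#' @return numeric vector of the same length as `ma` (leading `NA`).
#' @export
slope <- function(ma) {
  if (length(ma) < 2L) .stopf("need at least 2 points")
  c(NA_real_, diff(ma))
}

#' Detect the accuracy plateau and choose the marker budget
#'
#' Smooths the size-accuracy curve with a trailing moving average, takes
#' first differences, and declares a plateau at the first index `t` where
#' either (a) `|Slope_t| < near_zero_eps * max(Slope)` holds for `run_length`
#' consecutive intervals (the first interval of the run is taken), or (b)
#' `Slope_t < (1 - drop_frac) * mean(Slope over all earlier intervals)`
#' (requires a positive prior mean). The returned budget is the grid size at
#' the left end of the triggering interval - the first point of the stable
#' region. When no rule fires the largest grid size is returned with a
#' warning.
#'
#' @param curve an `accuracy_curve` (or any `data.frame` with `size` and
#'   `mean_acc`).
#' @param cfg a [plateau_config()].
#' @return chosen subset size (integer); attributes `index` (position in the
#'   grid) and `rule` (`"near_zero"`, `"drop"` or `"none"`).
#' @export
detect_plateau <- function(curve, cfg = plateau_config()) {
  y <- curve$mean_acc
  sizes <- curve$size
  need <- cfg$ma_window + cfg$run_length + 1L
  if (length(y) < need)
    .stopf("curve too short (%d points) for window %d + run length %d",
           length(y), cfg$ma_window, cfg$run_length)
  sl <- slope(moving_average(y, cfg$ma_window))
  ts <- which(!is.na(sl))
  mx <- max(sl[ts])
  t_near <- NA_integer_
  if (!is.na(cfg$near_zero_eps) && mx > 0) {
    below <- abs(sl[ts]) < cfg$near_zero_eps * mx
    run <- 0L
    for (k in seq_along(ts)) {
      run <- if (below[k]) run + 1L else 0L
      if (run == cfg$run_length) { t_near <- ts[k - cfg$run_length + 1L]; break }
    }
  }
  t_drop <- NA_integer_
  if (!is.na(cfg$drop_frac)) {
    for (k in seq_along(ts)[-1L]) {
      ref <- if ((cfg$drop_ref %||% "all") == "window")
        ts[max(1L, k - cfg$ma_window):(k - 1L)]
      else ts[seq_len(k - 1L)]
      prior <- mean(sl[ref])
      if (prior > 0 && sl[ts[k]] < (1 - cfg$drop_frac) * prior) {
        t_drop <- ts[k]; break
      }
    }
  }
  t_star <- suppressWarnings(min(t_near, t_drop, na.rm = TRUE))
  if (!is.finite(t_star)) {
    .warnf("no plateau detected; falling back to the largest grid size")
    return(structure(sizes[length(sizes)], index = length(sizes), rule = "none"))
  }
  rule <- if (!is.na(t_near) && t_star == t_near) "near_zero" else "drop"
  idx <- max(t_star - 1L, 1L)  # left end of the triggering interval
  structure(sizes[idx], index = idx, rule = rule)
}
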