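#' Synthetic-data configuration
#'
#' Defines the desk-scale world the test fixtures live in: LD-blocked
#' biallelic genotypes for a random-mating population, non-overlapping gene
#' models annotated to GO terms, and an additive polygenic trait whose
#' causal markers (QTNs) are enriched inside GO-annotated genes. Defaults
#' give a full-pipeline run that fits in minutes on one core while keeping
#' the tagging structure the selection method exploits.
#'
#' @param n_samples number of diploid samples.
#' @param n_markers total marker count (split evenly across chromosomes).
#' @param n_chrom number of chromosomes.
#' @param ld_block_len markers per LD block.
#' @param within_block_rho lag-1 latent correlation inside a block (blocks
#'   are independent).
#' @param maf_range allele-frequency range markers are drawn from.
#' @param n_genes number of non-overlapping genes.
#' @param n_terms number of GO terms.
#' @param qtn_count number of causal markers.
#' @param qtn_in_go_frac fraction of QTNs placed inside GO-annotated genes.
#' @param h2 narrow-sense heritability, matched exactly in-sample.
#' @param seed integer seed; every generator is deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_markers = 5000L, n_chrom = 5L,
                       ld_block_len = 25L, within_block_rho = 0.9,
                       maf_range = c(0.05, 0.5), n_genes = 50L, n_terms = 12L,
                       qtn_count = 30L, qtn_in_go_frac = 0.8, h2 = 0.7,
                       seed = 1L) {
  stopifnot(h2 > 0, h2 < 1, qtn_count < n_markers,
            within_block_rho >= 0, within_block_rho < 1,
            maf_range[1L] > 0, maf_range[2L] <= 0.5, n_chrom >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate LD-blocked genotypes
#'
#' Two haplotypes per sample are drawn from a latent lag-1 autoregressive
#' Gaussian within each LD block (blocks independent) and thresholded at
#' per-marker allele frequencies drawn uniformly from `maf_range`, then
#' summed to dosages. Adjacent markers within a block are therefore
#' correlated with latent correlation `within_block_rho^d` at distance `d`,
#' while markers in different blocks are independent.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    m_per <- rep(cfg$n_markers %/% cfg$n_chrom, cfg$n_chrom)
    m_per[seq_len(cfg$n_markers %% cfg$n_chrom)] <-
      m_per[seq_len(cfg$n_markers %% cfg$n_chrom)] + 1L
    nh <- 2L * cfg$n_samples
    rho <- cfg$within_block_rho
    dos_list <- vector("list", cfg$n_chrom)
    mk_list <- vector("list", cfg$n_chrom)
    for (ch in seq_len(cfg$n_chrom)) {
      m <- m_per[ch]
      p <- stats::runif(m, cfg$maf_range[1L], cfg$maf_range[2L])
      Z <- matrix(NA_real_, nh, m)
      blk <- rep(seq_len(ceiling(m / cfg$ld_block_len)),
                 each = cfg$ld_block_len, length.out = m)
      newblk <- c(TRUE, blk[-1L] != blk[-m])
      Z[, 1L] <- stats::rnorm(nh)
      if (m > 1L) for (j in 2:m) {
        Z[, j] <- if (newblk[j]) stats::rnorm(nh)
                  else rho * Z[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(nh)
      }
      hap <- Z < matrix(stats::qnorm(p), nh, m, byrow = TRUE)
      dos_list[[ch]] <- hap[seq_len(cfg$n_samples), , drop = FALSE] +
        hap[cfg$n_samples + seq_len(cfg$n_samples), , drop = FALSE]
      pos <- sort(sample.int(m * 100L, m))
      mk_list[[ch]] <- data.frame(
        id = sprintf("snp_c%d_%05d", ch, seq_len(m)),
        chrom = sprintf("chr%d", ch), pos = pos, ref = "A", alt = "C",
        stringsAsFactors = FALSE)
    }
    genotype_matrix(do.call(cbind, dos_list) * 1L, do.call(rbind, mk_list),
                    sprintf("s%04d", seq_len(cfg$n_samples)))
  })
}

#' Simulate gene models and a GO annotation map
#'
#' Genes are non-overlapping intervals tiled over the marker positions of
#' the simulated genome (so each SNP maps to at most one gene); GO terms
#' receive random gene sets of varying size, so that the marker counts of
#' different terms straddle any reasonable effective-term threshold.
#'
#' @param cfg a [sim_config()].
#' @param geno the [genotype_matrix()] from [simulate_genotypes()] (same
#'   config).
#' @return list with `genes` (gene-model `data.frame`, 0-based half-open)
#'   and `go` (named term -> genes list of class `go_map`).
#' @export
simulate_annotation <- function(cfg, geno) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotype_matrix"))
  withr::with_seed(cfg$seed + 1L, {
    chroms <- unique(geno$markers$chrom)
    per_chrom <- rep(cfg$n_genes %/% length(chroms), length(chroms))
    per_chrom[seq_len(cfg$n_genes %% length(chroms))] <-
      per_chrom[seq_len(cfg$n_genes %% length(chroms))] + 1L
    genes <- list()
    gid <- 0L
    for (ci in seq_along(chroms)) {
      mk <- geno$markers[geno$markers$chrom == chroms[ci], ]
      m <- nrow(mk)
      ng <- per_chrom[ci]
      if (!ng) next
      ## carve [1, m] into ng disjoint marker runs with random gaps; the gene
      ## interval covers its run exactly, so genes can never overlap
      span_len <- pmax(3L, stats::rpois(ng, m %/% (2L * ng)))
      gaps <- stats::rmultinom(1L, max(m - sum(span_len), 0L), rep(1, ng + 1L))[, 1L]
      cursor <- 1L
      for (g in seq_len(ng)) {
        first <- cursor + gaps[g]
        if (first > m) break
        last <- min(first + span_len[g] - 1L, m)
        cursor <- last + 1L
        gid <- gid + 1L
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene%03d", gid), chrom = chroms[ci],
          start = mk$pos[first] - 1L,  # 0-based half-open over the marker run
          end = mk$pos[last],
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, genes)
    sizes <- pmax(1L, stats::rbinom(cfg$n_terms, nrow(genes),
                                    stats::runif(cfg$n_terms, 0.05, 0.5)))
    go <- lapply(sizes, function(s) sort(sample(genes$gene_id, min(s, nrow(genes)))))
    names(go) <- sprintf("GO:%07d", seq_len(cfg$n_terms))
    class(go) <- "go_map"
    list(genes = genes, go = go)
  })
}

#' Simulate an additive polygenic phenotype with planted QTNs
#'
#' Picks `qtn_count` causal markers, a fraction `qtn_in_go_frac` of them
#' inside GO-annotated genes, draws standard-normal effect sizes, and forms
#' `y = W beta + e` from the centered QTN dosages. The noise is
#' orthogonalized against the genetic values and rescaled so that the
#' in-sample variance ratio equals `h2` exactly.
#'
#' @param geno the simulated [genotype_matrix()].
#' @param genes,go output of [simulate_annotation()].
#' @param cfg the [sim_config()].
#' @param trait_name trait column name.
#' @return list with `pheno` (a `phenotype_table`) and `qtn` (truth table:
#'   `marker_id`, `beta`, `in_go`).
#' @export
simulate_phenotype <- function(geno, genes, go, cfg, trait_name = "y") {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 2L, {
    annotated <- unique(unlist(go, use.names = FALSE))
    gsub_ <- genes[genes$gene_id %in% annotated, , drop = FALSE]
    mk <- geno$markers
    in_go <- rep(FALSE, nrow(mk))
    for (i in seq_len(nrow(gsub_))) {
      in_go <- in_go | (mk$chrom == gsub_$chrom[i] &
                          mk$pos - 1L >= gsub_$start[i] & mk$pos - 1L < gsub_$end[i])
    }
    n_in <- round(cfg$qtn_in_go_frac * cfg$qtn_count)
    if (n_in > sum(in_go))
      .stopf("requested %d in-gene QTNs but only %d markers fall in GO-annotated genes",
             n_in, sum(in_go))
    qtn_in <- sample(mk$id[in_go], n_in)
    qtn_out <- sample(setdiff(mk$id, mk$id[in_go]), cfg$qtn_count - n_in)
    qtn <- c(qtn_in, qtn_out)
    beta <- stats::rnorm(cfg$qtn_count)
    W <- scale(.impute_mean(geno$dosages[, qtn, drop = FALSE]), scale = FALSE)
    g <- drop(W %*% beta)
    if (stats::var(g) == 0) .stopf("degenerate genetic values (all QTNs monomorphic)")
    e <- stats::rnorm(length(g))
    e <- e - mean(e)
    gc <- g - mean(g)
    e <- e - gc * sum(e * gc) / sum(gc^2)      # exact in-sample orthogonality
    e <- e * sqrt(stats::var(g) * (1 - cfg$h2) / (cfg$h2 * stats::var(e)))
    y <- g + e
    pheno <- data.frame(sample_id = geno$sample_ids, y = y,
                        stringsAsFactors = FALSE)
    names(pheno)[2L] <- trait_name
    class(pheno) <- c("phenotype_table", "data.frame")
    list(pheno = pheno,
         qtn = data.frame(marker_id = qtn, beta = beta,
                          in_go = qtn %in% qtn_in, stringsAsFactors = FALSE))
  })
}

#' Generate and optionally write a complete synthetic fixture set
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_annotation()] and [simulate_phenotype()]; with `dir` set it
#' also writes `genotypes.vcf`, `phenos.tsv`, `genes.gff3`, `go_map.tsv`
#' and `qtn_truth.tsv` so the I/O readers can be exercised end to end.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @return list with `geno`, `genes`, `go`, `pheno`, `qtn` (and `dir` when
#'   written).
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  geno <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, geno)
  ph <- simulate_phenotype(geno, ann$genes, ann$go, cfg)
  out <- list(geno = geno, genes = ann$genes, go = ann$go,
              pheno = ph$pheno, qtn = ph$qtn)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(geno, file.path(dir, "genotypes.vcf"))
    write_phenotypes(ph$pheno, file.path(dir, "phenos.tsv"))
    write_gff3(ann$genes, file.path(dir, "genes.gff3"))
    write_go_map(ann$go, file.path(dir, "go_map.tsv"))
    utils::write.table(ph$qtn, file.path(dir, "qtn_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$dir <- dir
  }
  out
}
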