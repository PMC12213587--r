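#' In-memory genotype container
#'
#' Bundles a samples x markers dosage matrix (counts of the alternate allele,
#' `0/1/2`, `NA` for missing calls) with per-marker metadata and sample
#' identifiers. Markers are stored coordinate-sorted by `(chrom, pos)`; the
#' dosage columns are reordered accordingly.
#'
#' @param dosages numeric or integer matrix, `n_samples x n_markers`, values
#'   in `{0, 1, 2, NA}`.
#' @param markers `data.frame` with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per dosage column, ids unique.
#' @param sample_ids character vector, one per dosage row.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages`, `markers`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, markers, sample_ids) {
  dosages <- as.matrix(dosages)
  if (!is.data.frame(markers)) markers <- as.data.frame(markers)
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(markers))
  if (length(miss)) .stopf("markers lacks column(s): %s", paste(miss, collapse = ", "))
  if (ncol(dosages) != nrow(markers))
    .stopf("dosages has %d columns but markers has %d rows", ncol(dosages), nrow(markers))
  if (nrow(dosages) != length(sample_ids))
    .stopf("dosages has %d rows but %d sample ids supplied", nrow(dosages), length(sample_ids))
  if (anyDuplicated(markers$id)) .stopf("marker ids are not unique")
  if (anyDuplicated(sample_ids)) .stopf("sample ids are not unique")
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (any(markers$pos < 1L, na.rm = TRUE)) .stopf("marker positions must be >= 1")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) .stopf("dosages must be 0, 1, 2 or NA (%d offending cells)", sum(bad))
  ord <- order(markers$chrom, markers$pos, markers$id)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(sample_ids, markers$id)
  structure(list(dosages = dosages, markers = markers,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$markers$chrom))))
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss, 100 * nmiss / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param geno a [genotype_matrix()].
#' @param samples sample ids or row indices to keep (`NULL` keeps all).
#' @param markers marker ids or column indices to keep (`NULL` keeps all).
#'   Genomic order is preserved regardless of the order given.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, samples = NULL, markers = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ridx <- seq_along(geno$sample_ids)
  if (!is.null(samples)) {
    ridx <- if (is.character(samples)) match(samples, geno$sample_ids) else as.integer(samples)
    if (anyNA(ridx)) .stopf("unknown sample id(s)")
  }
  cidx <- seq_len(nrow(geno$markers))
  if (!is.null(markers)) {
    cidx <- if (is.character(markers)) match(markers, geno$markers$id) else as.integer(markers)
    if (anyNA(cidx)) .stopf("unknown marker id(s)")
    cidx <- sort(cidx)
  }
  genotype_matrix(geno$dosages[ridx, cidx, drop = FALSE],
                  geno$markers[cidx, , drop = FALSE],
                  geno$sample_ids[ridx])
}
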