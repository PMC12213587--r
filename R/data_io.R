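## On-disk formats. Genotypes: VCF 4.x (GT field), PLINK 1 bed/bim/fam, or a
## plain sample x marker dosage TSV. Gene models: GFF3 or BED4. Phenotypes and
## GO maps: TSV. Internally all interval coordinates are 0-based half-open;
## user-facing formats keep their native convention.

.GT_DOSAGE <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
                "1|0" = 1, "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA,
                "0" = 0, "1" = 1, "." = NA, "./0" = NA, "0/." = NA,
                "./1" = NA, "1/." = NA)

#' Read genotypes into a [genotype_matrix()]
#'
#' Supported dialects: VCF 4.x (`GT` field; parsed with
#' \pkg{VariantAnnotation}), PLINK 1 binary (`.bed`/`.bim`/`.fam` triplet,
#' SNP-major), and a dosage TSV whose first column is `sample_id` and whose
#' remaining columns are markers. Only biallelic SNVs are kept; multi-allelic
#' VCF records are skipped with a warning. Dosage is the alternate-allele
#' count; missing calls stay `NA`.
#'
#' For the TSV dialect, marker coordinates are recovered from column names of
#' the form `chrom:pos[_ref_alt]` when present, otherwise markers are placed
#' on a pseudo-chromosome `"0"` at their column index.
#'
#' @param path file path. For PLINK, the `.bed` path or the common prefix.
#' @param format one of `"vcf"`, `"plink"`, `"tsv"`.
#' @return a [genotype_matrix()], markers coordinate-sorted.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink", "tsv")) {
  format <- match.arg(format)
  switch(format,
         vcf = .read_vcf(path),
         plink = read_plink(path),
         tsv = .read_dosage_tsv(path))
}

.read_vcf <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  keep <- nalt == 1L
  if (any(!keep))
    .warnf("skipping %d multi-allelic record(s)", sum(!keep))
  if (!sum(keep)) .stopf("no biallelic records in %s", path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) .stopf("VCF has no GT field: %s", path)
  gt <- gt[keep, , drop = FALSE]
  dos <- .GT_DOSAGE[gt]
  unknown <- is.na(dos) & !(gt %in% names(.GT_DOSAGE))
  if (any(unknown))
    .warnf("%d unrecognized GT value(s) treated as missing (e.g. '%s')",
           sum(unknown), gt[unknown][1L])
  dos <- matrix(dos, nrow = sum(keep), dimnames = NULL)
  markers <- data.frame(
    id = names(rr)[keep],
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = as.character(VariantAnnotation::ref(vcf))[keep],
    alt = as.character(unlist(alt[keep])),
    stringsAsFactors = FALSE)
  genotype_matrix(t(dos), markers, colnames(gt))
}

.read_dosage_tsv <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE)
  if (names(dt)[1L] != "sample_id")
    .stopf("dosage TSV must start with a 'sample_id' column")
  ids <- as.character(dt[[1L]])
  X <- as.matrix(dt[, -1L, drop = FALSE])
  mk <- colnames(X)
  parsed <- regmatches(mk, regexec("^([^:]+):(\\d+)(?:_([A-Za-z]+)_([A-Za-z]+))?$", mk))
  ok <- lengths(parsed) == 5L & vapply(parsed, function(p) nzchar(p[2L]), TRUE)
  markers <- data.frame(id = mk, chrom = "0", pos = seq_along(mk),
                        ref = "A", alt = "B", stringsAsFactors = FALSE)
  if (all(ok)) {
    markers$chrom <- vapply(parsed, `[`, "", 2L)
    markers$pos <- as.integer(vapply(parsed, `[`, "", 3L))
    rf <- vapply(parsed, `[`, "", 4L)
    al <- vapply(parsed, `[`, "", 5L)
    markers$ref <- ifelse(nzchar(rf), rf, "A")
    markers$alt <- ifelse(nzchar(al), al, "B")
  }
  genotype_matrix(X, markers, ids)
}

#' Read a phenotype table
#'
#' Expects a TSV with a header line `sample_id` plus one column per trait;
#' `NA` marks missing values. Row order is preserved.
#'
#' @param path file path.
#' @return `data.frame` of class `phenotype_table` with `sample_id` plus
#'   numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE, colClasses = list(character = 1L))
  if (names(dt)[1L] != "sample_id")
    .stopf("phenotype TSV must start with a 'sample_id' column")
  if (anyDuplicated(dt$sample_id))
    .stopf("duplicate sample_id in %s", path)
  for (j in seq_along(dt)[-1L]) {
    v <- dt[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        .stopf("non-numeric value '%s' in trait '%s'", v[bad[1L]], names(dt)[j])
      v <- num
    }
    dt[[j]] <- as.numeric(v)
  }
  class(dt) <- c("phenotype_table", "data.frame")
  dt
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 rows of type `gene` must carry an `ID` attribute; their 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention. BED input (0-based half-open, 4th column = gene id) is taken
#' as-is.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`+`, `-` or `.`).
#' @export
read_gene_models <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[gr$type == "gene"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      .stopf("GFF3 gene record without an ID attribute in %s", path)
  } else {
    ids <- gr$name
    if (is.null(ids) || anyNA(ids)) .stopf("BED input needs a 4th (name) column")
  }
  ## rtracklayer presents both formats as 1-based closed ranges
  out <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  if (any(out$start > out$end)) .stopf("gene with start > end in %s", path)
  rownames(out) <- NULL
  out
}

#' Read a GO-term-to-gene annotation map
#'
#' Two-column TSV (`term_id`, `gene_id`), duplicates allowed and collapsed.
#' The map is expected to be already propagated through subordinate terms.
#' Rows whose term id does not match `GO:` followed by seven digits are
#' skipped with a warning.
#'
#' @param path file path.
#' @return named list mapping term id to a character vector of gene ids
#'   (class `go_map`).
#' @export
read_go_map <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2L) .stopf("GO map must have two columns (term_id, gene_id)")
  term <- dt[[1L]]; gene <- dt[[2L]]
  ## tolerate a header line
  if (nrow(dt) && grepl("term", term[1L], ignore.case = TRUE)) {
    term <- term[-1L]; gene <- gene[-1L]
  }
  ok <- grepl("^GO:\\d{7}$", term)
  if (any(!ok)) .warnf("skipping %d row(s) with malformed GO term ids", sum(!ok))
  term <- term[ok]; gene <- gene[ok]
  if (!length(term)) .stopf("no valid rows in GO map %s", path)
  m <- lapply(split(gene, term), function(g) sort(unique(g)))
  structure(m[order(names(m))], class = "go_map")
}

#' @export
print.go_map <- function(x, ...) {
  cat(sprintf("go_map: %d terms, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Write / read a marker-subset list
#'
#' A marker subset is stored as plain text, one marker id per line, in the
#' order given. When `geno` is supplied, every id must exist in it.
#'
#' @param subset character vector of marker ids.
#' @param path output file.
#' @param geno optional [genotype_matrix()] used to validate the ids.
#' @return `write_marker_subset()` returns `path` invisibly;
#'   `read_marker_subset()` returns a character vector.
#' @export
write_marker_subset <- function(subset, path, geno = NULL) {
  subset <- as.character(subset)
  if (!is.null(geno)) {
    bad <- setdiff(subset, geno$markers$id)
    if (length(bad))
      .stopf("unknown marker id(s): %s%s", paste(utils::head(bad, 5), collapse = ", "),
             if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  }
  writeLines(subset, path)
  invisible(path)
}

#' @rdname write_marker_subset
#' @export
read_marker_subset <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  x <- readLines(path)
  x[nzchar(x)]
}
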