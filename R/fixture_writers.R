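## Plain-text writers for the formats the synthetic generator emits. Readers
## for these formats go through VariantAnnotation / rtracklayer, so writing
## and reading exercise two independent code paths.

#' Write a genotype matrix as an uncompressed VCF 4.2 file
#'
#' Emits GT-only biallelic records (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param geno a [genotype_matrix()].
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  mk <- geno$markers
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_of[as.character(geno$dosages)], nrow = nrow(geno$dosages))
  gt[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bingogs-simulator",
    sprintf("##contig=<ID=%s>", unique(mk$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive GFF3 convention.
#'
#' @param genes gene-model `data.frame` as returned by [read_gene_models()].
#' @param path output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
  lines <- paste(genes$chrom, "bingogs", "gene", genes$start + 1L, genes$end,
                 ".", strand, ".", sprintf("ID=%s", genes$gene_id), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a phenotype table / GO map as TSV
#'
#' @param pheno `data.frame` with a `sample_id` column plus trait columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @param go named list mapping GO term ids to gene-id vectors.
#' @export
write_go_map <- function(go, path) {
  df <- data.frame(term_id = rep(names(go), lengths(go)),
                   gene_id = unlist(go, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
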