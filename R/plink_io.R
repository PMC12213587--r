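## PLINK 1 binary genotypes. The .bed payload is SNP-major: per marker,
## ceiling(n/4) bytes, two bits per sample (low bits first within a byte),
## coded 00 = hom A1, 10 = het, 11 = hom A2, 01 = missing. We store the
## alternate allele as A1, so dosage(alt) maps 2 -> 00, 1 -> 10, 0 -> 11.

.plink_prefix <- function(path) sub("\\.bed$", "", path)

#' Read / write PLINK 1 binary genotypes
#'
#' `read_plink()` parses a `.bed`/`.bim`/`.fam` triplet (SNP-major layout
#' only) into a [genotype_matrix()]; `write_plink()` does the reverse.
#' In the `.bim` file, A1 is taken as the alternate allele whose copies the
#' dosage counts, A2 as the reference.
#'
#' @param path `.bed` file path or the common prefix of the triplet.
#' @return `read_plink()`: a [genotype_matrix()]. `write_plink()`: the prefix,
#'   invisibly.
#' @export
read_plink <- function(path) {
  prefix <- .plink_prefix(path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) .stopf("no such file: %s", f)
  bimdt <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  famdt <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famdt); m <- nrow(bimdt)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    .stopf("%s is not a PLINK .bed file", bed)
  if (raw[3L] != as.raw(0x01))
    .stopf("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)
  if (length(raw) - 3L != bpm * m)
    .stopf(".bed payload size does not match %d samples x %d markers", n, m)
  bits <- matrix(as.integer(rawToBits(raw[-(1:3)])), nrow = 8L * bpm)
  codes <- bits[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    2L * bits[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  dos <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], nrow = n)
  markers <- data.frame(id = bimdt$id, chrom = as.character(bimdt$chrom),
                        pos = bimdt$pos, ref = bimdt$a2, alt = bimdt$a1,
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, markers, as.character(famdt[[2L]]))
}

#' @rdname read_plink
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix (`prefix.bed` etc. are written).
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosages); m <- ncol(geno$dosages)
  mk <- geno$markers
  utils::write.table(data.frame(mk$chrom, mk$id, 0L, mk$pos, mk$alt, mk$ref),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(geno$sample_ids, geno$sample_ids, 0L, 0L, 0L, -9L),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # dosage -> 2-bit code, NA -> 1
  pad <- (-n) %% 4L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    d <- geno$dosages[, j]
    code <- ifelse(is.na(d), 1L, code_of[as.character(d)])
    code <- c(code, rep(0L, pad))
    bits <- rbind(code %% 2L, code %/% 2L)  # low bit first
    writeBin(packBits(as.logical(bits), type = "raw"), con)
  }
  invisible(prefix)
}
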