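test_that("VCF reading: dosage coding, missing calls, multi-allelic skip", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\tm1\tA\tC\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\tm2\tG\tT\t.\tPASS\t.\tGT\t./.",
    "chr1\t300\tm3\tA\tC,G\t.\tPASS\t.\tGT\t1/2"), vcf)
  expect_warning(g <- read_genotypes(vcf, "vcf"), "multi-allelic")
  expect_equal(ncol(g$dosages), 2L)
  expect_equal(unname(g$dosages[1, "m1"]), 1)       # 0/1 -> one alt allele
  expect_true(is.na(g$dosages[1, "m2"]))            # ./. -> missing, not 0
  expect_equal(g$markers$pos, c(100L, 200L))
})

test_that("VCF round trip through write_vcf + read_genotypes", {
  d <- fx_small()
  sub <- subset_genotypes(d$geno, samples = 1:3, markers = 1:40)
  sub$dosages[2, 5] <- NA  # make sure a missing call survives the trip
  f <- tempfile(fileext = ".vcf")
  write_vcf(sub, f)
  back <- read_genotypes(f, "vcf")
  expect_identical(back$sample_ids, sub$sample_ids)
  expect_identical(back$markers, sub$markers)
  expect_equal(unname(back$dosages), unname(sub$dosages))
})

test_that("PLINK bed round trip and byte-level oracle", {
  d <- fx_small()
  sub <- subset_genotypes(d$geno, samples = 1:7, markers = 1:25)
  sub$dosages[3, 2] <- NA
  prefix <- tempfile()
  write_plink(sub, prefix)
  back <- read_plink(prefix)
  expect_identical(back$markers$id, sub$markers$id)
  expect_equal(unname(back$dosages), unname(sub$dosages))

  ## hand-constructed .bed: 4 samples, 1 marker, dosages (2, 1, 0, NA).
  ## two-bit codes (value = low bit + 2 * high bit): alt-hom 0, het 2,
  ## ref-hom 3, missing 1; packed low bits first within the byte:
  ## bit sequence 00 01 11 10 -> byte 0b01111000 = 0x78
  p2 <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x78)), paste0(p2, ".bed"))
  writeLines("1\tmA\t0\t50\tC\tA", paste0(p2, ".bim"))
  writeLines(sprintf("f%d\ti%d\t0\t0\t0\t-9", 1:4, 1:4), paste0(p2, ".fam"))
  g <- read_plink(p2)
  expect_equal(unname(g$dosages[, 1]), c(2, 1, 0, NA))
})

test_that("phenotype table reading: counts, empty file, error paths", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttr", paste0("s", 1:5, "\t", c(1, 2, "NA", 4, 5))), f)
  ph <- read_phenotypes(f)
  expect_s3_class(ph, "phenotype_table")
  expect_equal(sum(!is.na(ph$tr)), 4L)

  writeLines("sample_id\ttr", f)
  expect_equal(nrow(read_phenotypes(f)), 0L)

  writeLines(c("sample_id\ttr", "s1\t1", "s1\t2"), f)
  expect_error(read_phenotypes(f), "duplicate")
  writeLines(c("sample_id\ttr", "s1\tabc"), f)
  expect_error(read_phenotypes(f), "non-numeric")
})

test_that("phenotype fixture round trip preserves shape and trait names", {
  d <- fx_small()
  ph <- d$pheno
  ph$second <- ph$y * 2
  f <- tempfile(fileext = ".tsv")
  write_phenotypes(ph, f)
  back <- read_phenotypes(f)
  expect_equal(setdiff(names(back), "sample_id"), c("y", "second"))
  expect_equal(back$y, ph$y, tolerance = 1e-12)
  expect_equal(nrow(back), nrow(ph))
})

test_that("gene models: coordinate conventions and GFF3 involution", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=geneA",
               "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=rnaA;Parent=geneA"), gff)
  gm <- read_gene_models(gff, "gff3")
  expect_equal(nrow(gm), 1L)  # non-gene rows ignored
  expect_equal(gm$start, 0L)  # 1-based inclusive -> 0-based half-open
  expect_equal(gm$end, 100L)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tgeneA", bed)
  gb <- read_gene_models(bed, "bed")
  expect_equal(gb[, c("start", "end")], gm[, c("start", "end")])

  d <- fx_small()
  f2 <- tempfile(fileext = ".gff3")
  write_gff3(d$genes, f2)
  back <- read_gene_models(f2, "gff3")
  expect_equal(nrow(back), nrow(d$genes))
  expect_equal(back[order(back$gene_id), c("gene_id", "chrom", "start", "end")],
               d$genes[order(d$genes$gene_id), c("gene_id", "chrom", "start", "end")],
               ignore_attr = TRUE)
})

test_that("GO map reading: dedup, malformed ids, propagation containment", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("GO:0000001\tg1", "GO:0000001\tg1", "GO:0000002\tg2",
               "GO:1\tg3"), f)
  expect_warning(m <- read_go_map(f), "malformed")
  expect_length(m, 2L)
  expect_equal(m[["GO:0000001"]], "g1")  # duplicate row collapsed

  ## propagated parent term contains the child's genes
  writeLines(c("GO:0000010\tg1", "GO:0000010\tg2", "GO:0000010\tg3",
               "GO:0000011\tg2"), f)
  m2 <- read_go_map(f)
  expect_true(all(m2[["GO:0000011"]] %in% m2[["GO:0000010"]]))

  d <- fx_small()
  f2 <- tempfile(); write_go_map(d$go, f2)
  back <- read_go_map(f2)
  expect_equal(unclass(back)[order(names(back))],
               unclass(d$go)[order(names(d$go))], ignore_attr = TRUE)
})

test_that("marker-subset lists round-trip, including the empty case", {
  f <- tempfile()
  write_marker_subset(character(0), f)
  expect_length(read_marker_subset(f), 0L)
  d <- fx_small()
  ids <- sample(d$geno$markers$id, 1000)
  write_marker_subset(ids, f, geno = d$geno)
  expect_identical(read_marker_subset(f), ids)
  expect_error(write_marker_subset("nope", f, geno = d$geno), "unknown marker")
})

test_that("dosage TSV dialect recovers coordinates from column names", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchr2:50_A_G\tchr1:10_A_C",
               "s1\t0\t2", "s2\tNA\t1"), f)
  g <- read_genotypes(f, "tsv")
  expect_equal(g$markers$chrom, c("chr1", "chr2"))  # coordinate-sorted
  expect_equal(unname(g$dosages[, 1]), c(2, 1))
  expect_true(is.na(g$dosages["s2", "chr2:50_A_G"]))
})
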