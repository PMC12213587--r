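#' Map GO terms to SNP markers via gene intervals
#'
#' A SNP belongs to a term iff its position falls within
#' `[start - flank_bp, end + flank_bp)` (0-based half-open) of any gene
#' annotated to that term. The GO map is expected to be propagated already,
#' so a parent term's marker set is a superset of its children's. Gene ids in
#' the map that have no gene model are skipped with a warning.
#'
#' @param go a `go_map` from [read_go_map()] (or a plain named list
#'   term -> gene ids).
#' @param genes gene-model `data.frame` ([read_gene_models()]).
#' @param geno a [genotype_matrix()]; only its marker coordinates are used.
#' @param flank_bp symmetric flank added to each gene interval (default 0 =
#'   strict gene body).
#' @return list of class `term_marker_index` with `term_to_markers` (named
#'   list of marker-id vectors in genomic order), `effective_terms`
#'   (initially all non-empty terms) and `marker_universe` (all marker ids in
#'   genomic order, used for ordering unions).
#' @export
map_terms_to_markers <- function(go, genes, geno, flank_bp = 0L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  all_genes <- unique(unlist(go, use.names = FALSE))
  unresolved <- setdiff(all_genes, genes$gene_id)
  if (length(unresolved))
    .warnf("%d gene id(s) in the GO map have no gene model and are skipped",
           length(unresolved))
  mk <- geno$markers
  snp_gr <- GenomicRanges::GRanges(mk$chrom, IRanges::IRanges(mk$pos, mk$pos))
  ## half-open [start - flank, end + flank) in 0-based coords equals the
  ## 1-based closed interval [start - flank + 1, end + flank]
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - flank_bp + 1L, 1L),
                     pmax(genes$end + flank_bp, genes$start - flank_bp + 1L)))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  gene_markers <- split(S4Vectors::queryHits(hits),
                        genes$gene_id[S4Vectors::subjectHits(hits)])
  term_to_markers <- lapply(go, function(gs) {
    idx <- sort(unique(unlist(gene_markers[intersect(gs, names(gene_markers))],
                              use.names = FALSE)))
    mk$id[idx]
  })
  if (!sum(lengths(term_to_markers)))
    .stopf("no SNP falls inside any GO-annotated gene: the prior is uninformative")
  structure(list(term_to_markers = term_to_markers,
                 effective_terms = names(term_to_markers)[lengths(term_to_markers) > 0],
                 marker_universe = mk$id),
            class = "term_marker_index")
}

#' @export
print.term_marker_index <- function(x, ...) {
  sz <- lengths(x$term_to_markers)
  cat(sprintf("term_marker_index: %d terms (%d effective), marker counts %d-%d\n",
              length(sz), length(x$effective_terms),
              if (length(sz)) min(sz) else 0L, if (length(sz)) max(sz) else 0L))
  invisible(x)
}

#' Retain GO terms with adequate marker representation
#'
#' A term is effective iff it maps to strictly more than `min_snps` markers.
#' An optional include/exclude list stands in for manual trait-relevance
#' curation; by default no curation is applied.
#'
#' @param idx a `term_marker_index`.
#' @param min_snps size threshold (strict `>`).
#' @param include_terms optional term ids to restrict to (applied before the
#'   size rule).
#' @param exclude_terms optional term ids to drop.
#' @return the index with `effective_terms` updated.
#' @export
select_effective_terms <- function(idx, min_snps = 200L, include_terms = NULL,
                                   exclude_terms = NULL) {
  stopifnot(inherits(idx, "term_marker_index"))
  terms <- names(idx$term_to_markers)
  if (!is.null(include_terms)) terms <- intersect(terms, include_terms)
  if (!is.null(exclude_terms)) terms <- setdiff(terms, exclude_terms)
  eff <- terms[lengths(idx$term_to_markers[terms]) > min_snps]
  if (!length(eff)) message("select_effective_terms: no term passes the size rule")
  idx$effective_terms <- eff
  idx
}

#' Merge effective terms into the GO marker pool
#'
#' Union of the effective terms' marker sets, deduplicated, in genomic order.
#'
#' @param idx a `term_marker_index` after [select_effective_terms()].
#' @return character vector of marker ids.
#' @export
build_go_pool <- function(idx) {
  stopifnot(inherits(idx, "term_marker_index"))
  pool <- unique(unlist(idx$term_to_markers[idx$effective_terms],
                        use.names = FALSE))
  idx$marker_universe[idx$marker_universe %in% pool]
}
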