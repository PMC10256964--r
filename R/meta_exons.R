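#' Collapse a gene's annotated exons into meta-exons
#'
#' All overlapping exons of one gene (across its transcripts) are merged
#' into a single "meta-exon", the analysis unit that absorbs alternative
#' splice sites, alternative transcription starts and alternative
#' polyadenylation. Exons overlapping by at least 1 nt are merged;
#' bookended exons that share only a boundary coordinate are not, since
#' half-open intervals do not overlap. Each meta-exon carries the IDs of
#' every transcript contributing an overlapping exon, and an
#' alternative/constitutive flag: a meta-exon is alternative iff at least
#' one transcript of the gene has no exon overlapping it.
#'
#' @param ann an `emats_annotation`, or a data.frame shaped like its
#'   `exons` element.
#' @param gene_id optional single gene to collapse; default all genes.
#' @return data.frame with one row per meta-exon: `exon_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `transcripts` (comma-separated),
#'   `n_supporting`, `is_alternative`. Meta-exons are numbered in
#'   transcription order within each gene.
#' @examples
#' ex <- data.frame(gene_id = "g1", transcript_id = c("t1", "t2"),
#'                  chrom = "chr1", start = c(100L, 150L), end = c(200L, 250L),
#'                  strand = "+")
#' collapse_meta_exons(ex)  # one meta-exon [100, 250)
#' @export
collapse_meta_exons <- function(ann, gene_id = NULL) {
  exons <- if (inherits(ann, "emats_annotation")) ann$exons else ann
  if (!is.null(gene_id)) exons <- exons[exons$gene_id %in% gene_id, , drop = FALSE]
  if (nrow(exons) == 0L) stop("no exons to collapse")
  pieces <- lapply(split(exons, exons$gene_id), collapse_one_gene)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

collapse_one_gene <- function(ex) {
  if (length(unique(ex$chrom)) != 1L || length(unique(ex$strand)) != 1L)
    stop("gene ", ex$gene_id[1], ": exons span multiple chromosomes or strands")
  ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)  # closed for IRanges
  # min.gapwidth = 0: merge on >= 1 nt overlap only; bookended exons that
  # share a boundary coordinate do not overlap as half-open intervals
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  hits <- IRanges::findOverlaps(ir, red)
  tx_all <- unique(ex$transcript_id)
  sup <- lapply(seq_along(red), function(i) {
    unique(ex$transcript_id[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]])
  })
  strand <- ex$strand[1]
  start0 <- IRanges::start(red) - 1L
  end0 <- IRanges::end(red)
  ord <- order(tx_pos(five_prime(start0, end0, strand), strand))
  data.frame(
    exon_id = paste0(ex$gene_id[1], ":ME", seq_along(red)),
    gene_id = ex$gene_id[1], chrom = ex$chrom[1],
    start = start0[ord], end = end0[ord], strand = strand,
    transcripts = vapply(sup[ord], function(s) paste(sort(s), collapse = ","), ""),
    n_supporting = lengths(sup[ord]),
    is_alternative = lengths(sup[ord]) < length(tx_all),
    stringsAsFactors = FALSE)
}

#' Flag a meta-exon as alternative or constitutive
#'
#' A meta-exon is alternative iff at least one transcript of its gene has
#' no exon overlapping it; it is constitutive iff every transcript
#' overlaps it. Overlap is any-overlap at the meta-exon level, not exact
#' coordinate identity, because meta-exons absorb alternative splice
#' sites.
#'
#' @param meta one meta-exon row (from [collapse_meta_exons()]).
#' @param exons the gene's annotated exon data.frame.
#' @return logical: `TRUE` when alternative.
#' @export
flag_alternative <- function(meta, exons) {
  exons <- exons[exons$gene_id == meta$gene_id, , drop = FALSE]
  if (nrow(exons) == 0L) stop("gene ", meta$gene_id, " has no transcripts")
  ov <- exons$start < meta$end & exons$end > meta$start
  length(setdiff(unique(exons$transcript_id), unique(exons$transcript_id[ov]))) > 0L
}
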