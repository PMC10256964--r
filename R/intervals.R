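#' Strand-aware genomic interval helpers
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`,
#' the convention used by BED and by the gene-architecture formulas
#' (gene kilobase length, exon distance to the gene 5' coordinate).
#' GTF input (1-based, closed) is converted at the I/O boundary only.
#'
#' @param chrom character chromosome name(s).
#' @param start,end integer 0-based half-open bounds; `end > start`.
#' @param strand `"+"` or `"-"`.
#' @return `genome_interval` returns a data.frame with one row per interval
#'   and columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' gi <- genome_interval("chr1", 1000, 1200, "+")
#' five_prime(gi$start, gi$end, gi$strand)   # 1000
#' three_prime(gi$start, gi$end, gi$strand)  # 1200
#' @export
genome_interval <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  validate_interval(chrom, start, end, strand)
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

validate_interval <- function(chrom, start, end, strand) {
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval bounds must be non-missing integers")
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start (half-open)")
  bad <- !strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand symbol: ", paste(unique(strand[bad]), collapse = ", "))
  invisible(TRUE)
}

#' @rdname genome_interval
#' @details `five_prime()` / `three_prime()` return the boundary coordinate in
#'   transcription direction: on `+` the 5' boundary is `start` and the 3'
#'   boundary is `end`; on `-` they swap.
#' @export
five_prime <- function(start, end, strand) {
  n <- max(length(start), length(strand))
  ifelse(rep_len(strand == "+", n), rep_len(start, n), rep_len(end, n))
}

#' @rdname genome_interval
#' @export
three_prime <- function(start, end, strand) {
  n <- max(length(start), length(strand))
  ifelse(rep_len(strand == "+", n), rep_len(end, n), rep_len(start, n))
}

# Transcription-direction position of a boundary coordinate: monotone
# increasing along the direction of transcription on either strand.
tx_pos <- function(coord, strand) {
  n <- max(length(coord), length(strand))
  ifelse(rep_len(strand == "+", n), rep_len(coord, n), -rep_len(coord, n))
}

# Transcription-direction position of a 1-nt point [p, p+1). The -p-1 form
# keeps half-open containment tests exact on the minus strand.
tx_pos_point <- function(pos, strand) {
  n <- max(length(pos), length(strand))
  ifelse(rep_len(strand == "+", n), rep_len(pos, n), -rep_len(pos, n) - 1)
}

#' Gene length in kilobases
#'
#' Defined on 0-based half-open gene spans as `(end - start) / 1000`.
#'
#' @param start,end gene span bounds (0-based half-open).
#' @return numeric kilobases.
#' @examples
#' gene_length_kb(10000, 12500)  # 2.5
#' @export
gene_length_kb <- function(start, end) {
  if (any(end <= start)) stop("gene span end must be > start")
  (end - start) / 1000
}

#' Exon distance to the host gene's 5' coordinate
#'
#' `exon_start - gene_start` for forward-strand features and
#' `gene_end - exon_end` for reverse-strand features (0-based half-open).
#'
#' @param exon_start,exon_end exon bounds.
#' @param gene_start,gene_end host gene span bounds.
#' @param strand shared strand of exon and gene.
#' @return non-negative integer distance in nt.
#' @examples
#' exon_distance_to_gene_5prime(2000, 2100, 1000, 9000, "+")  # 1000
#' exon_distance_to_gene_5prime(7900, 8000, 1000, 9000, "-")  # 1000
#' @export
exon_distance_to_gene_5prime <- function(exon_start, exon_end,
                                         gene_start, gene_end, strand) {
  if (any(exon_start < gene_start | exon_end > gene_end))
    stop("exon lies outside the gene span")
  d <- ifelse(strand == "+", exon_start - gene_start, gene_end - exon_end)
  as.integer(d)
}
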