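#' Keep pathogenic and likely-pathogenic variants
#'
#' A record is retained when its clinical significance contains
#' "pathogenic" (case-insensitively) and does not contain "conflicting",
#' so "Pathogenic" and "Likely pathogenic" pass while "Benign",
#' "Uncertain significance" and "Conflicting interpretations of
#' pathogenicity" are dropped. Idempotent.
#'
#' @param variants variant data.frame with a `significance` column.
#' @return the pathogenic subset.
#' @export
filter_pathogenic <- function(variants) {
  if (!"significance" %in% names(variants))
    stop("variant table lacks a significance column")
  sig <- tolower(variants$significance)
  keep <- grepl("pathogenic", sig, fixed = TRUE) &
          !grepl("conflicting", sig, fixed = TRUE)
  out <- variants[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge a disease (morbid-map style) table with variants in EMATS genes
#'
#' Inner-joins variants to the gene-phenotype table on the gene column
#' (one output row per variant x phenotype), then keeps variants lying
#' inside the flanked wAFE/sSE regions of the catalog (exon interval
#' extended by `flank` nt on both sides).
#'
#' @param morbid_map data.frame with columns `gene_id` and `phenotype`.
#' @param variants variant data.frame (0-based `pos`; see
#'   [read_variants()]).
#' @param catalog an `emats_catalog`.
#' @param flank flank width in nt around each catalog exon.
#' @return annotated variant data.frame with `phenotype` and the matched
#'   `pair_id` / `exon_role`.
#' @export
merge_disease_tables <- function(morbid_map, variants, catalog, flank = 1000) {
  if (!all(c("gene_id", "phenotype") %in% names(morbid_map)))
    stop("morbid map lacks join columns gene_id / phenotype")
  ex <- catalog_exon_table(catalog)
  hits <- variants_in_regions(variants, ex, flank)
  if (nrow(hits) == 0L) return(hits[0, ])
  merged <- merge(hits, morbid_map[, c("gene_id", "phenotype")],
                  by = "gene_id", suffixes = c("", ".morbid"))
  merged$phenotype <- merged$phenotype.morbid
  merged$phenotype.morbid <- NULL
  rownames(merged) <- NULL
  merged
}

# unique (exon, role, pair) rows of a catalog
catalog_exon_table <- function(catalog) {
  p <- catalog$pairs
  if (nrow(p) == 0L)
    return(data.frame(gene_id = character(), pair_id = character(),
                      exon_role = character(), exon_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  ex <- rbind(
    data.frame(gene_id = p$gene_id, pair_id = p$pair_id, exon_role = "AFE",
               exon_id = p$wafe_id, chrom = p$chrom, start = p$wafe_start,
               end = p$wafe_end, strand = p$strand, stringsAsFactors = FALSE),
    data.frame(gene_id = p$gene_id, pair_id = p$pair_id, exon_role = "SE",
               exon_id = p$sse_id, chrom = p$chrom, start = p$sse_start,
               end = p$sse_end, strand = p$strand, stringsAsFactors = FALSE))
  ex
}

# variants within [start - flank, end + flank) of each catalog exon,
# replicated per overlapping exon; gene_id taken from the exon
variants_in_regions <- function(variants, exons, flank) {
  out <- list()
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    sel <- variants$chrom == e$chrom & variants$pos >= e$start - flank &
           variants$pos < e$end + flank
    if (!any(sel)) next
    v <- variants[sel, , drop = FALSE]
    v$gene_id <- e$gene_id
    v$pair_id <- e$pair_id
    v$exon_role <- e$exon_role
    v$exon_id <- e$exon_id
    out[[length(out) + 1L]] <- v
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      significance = character(), phenotype = character(),
                      pair_id = character(), exon_role = character(),
                      exon_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positional zone of a variant relative to an exon
#'
#' Strand-aware tiling of the exon's flank: in transcription direction,
#' `upstream` (from `-flank` to `-acc_w` before the exon start),
#' `tss_or_3ss` (the `acc_w` nt immediately 5' of the exon; the acceptor
#' side, which is the TSS-proximal region for an AFE and the 3' splice
#' site for an SE), `within_exon`, `fivess` (the `don_w` nt immediately
#' 3' of the exon end), and `downstream` (out to `+flank`). Positions
#' beyond the flank get `NA`. The five zones tile the flank with no gaps
#' or overlaps: their widths sum to `2 * flank + exon length`.
#'
#' @param pos variant position(s), 0-based (vector allowed).
#' @param exon one exon row (`chrom`, `start`, `end`, `strand`).
#' @param chrom chromosome of the variant(s).
#' @param acc_w acceptor-side window width, nt (default 25).
#' @param don_w donor-side window width, nt (default 6).
#' @param flank total flank width, nt (default 1000); must exceed both
#'   windows.
#' @return character vector of zones (NA outside the flank).
#' @examples
#' exon <- data.frame(chrom = "chr1", start = 3000L, end = 3100L, strand = "+")
#' classify_zone(3050, exon)            # within_exon
#' classify_zone(3102, exon)            # fivess
#' classify_zone(2950, exon)            # upstream
#' @export
classify_zone <- function(pos, exon, chrom = exon$chrom, acc_w = 25,
                          don_w = 6, flank = 1000) {
  if (!(acc_w < flank && don_w < flank))
    stop("splice-site windows must be smaller than the flank")
  if (any(chrom != exon$chrom))
    stop("variant chromosome does not match the exon")
  s <- tx_pos(five_prime(exon$start, exon$end, exon$strand), exon$strand)
  e <- tx_pos(three_prime(exon$start, exon$end, exon$strand), exon$strand)
  p <- tx_pos_point(pos, exon$strand)
  zone <- rep(NA_character_, length(p))
  zone[p >= s & p < e] <- "within_exon"
  zone[p >= s - acc_w & p < s] <- "tss_or_3ss"
  zone[p >= e & p < e + don_w] <- "fivess"
  zone[p >= s - flank & p < s - acc_w] <- "upstream"
  zone[p >= e + don_w & p < e + flank] <- "downstream"
  zone
}

#' Zone-annotate variants against every exon of an EMATS catalog
#'
#' @param variants variant data.frame (0-based `pos`).
#' @param catalog an `emats_catalog`.
#' @inheritParams classify_zone
#' @return data.frame of zone calls: one row per (variant, catalog exon)
#'   with the variant inside the exon's flank; columns include `zone`,
#'   `exon_role` (AFE/SE), `pair_id`, `exon_id`.
#' @export
annotate_variant_zones <- function(variants, catalog, acc_w = 25, don_w = 6,
                                   flank = 1000) {
  ex <- catalog_exon_table(catalog)
  ex <- ex[!duplicated(ex[, c("exon_id", "exon_role")]), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    sel <- which(variants$chrom == e$chrom &
                 variants$pos >= e$start - flank & variants$pos < e$end + flank)
    if (!length(sel)) next
    z <- classify_zone(variants$pos[sel], e, acc_w = acc_w, don_w = don_w,
                       flank = flank)
    keep <- !is.na(z)
    if (!any(keep)) next
    v <- variants[sel[keep], , drop = FALSE]
    v$zone <- z[keep]
    v$gene_id <- e$gene_id
    v$pair_id <- e$pair_id
    v$exon_role <- e$exon_role
    v$exon_id <- e$exon_id
    out[[length(out) + 1L]] <- v
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), zone = character(),
                      gene_id = character(), pair_id = character(),
                      exon_role = character(), exon_id = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count variants per zone and the regions they hit
#'
#' @param zone_calls output of [annotate_variant_zones()].
#' @return list with `per_zone` (named counts over the five zones),
#'   `n_window_regions` (distinct (exon, zone) windows hit by at least
#'   one variant) and `n_exon_regions` (distinct exons hit).
#' @export
count_zone_regions <- function(zone_calls) {
  zones <- c("upstream", "tss_or_3ss", "within_exon", "fivess", "downstream")
  per_zone <- stats::setNames(integer(length(zones)), zones)
  if (nrow(zone_calls)) {
    tab <- table(factor(zone_calls$zone, levels = zones))
    per_zone[] <- as.integer(tab)
  }
  list(per_zone = per_zone,
       n_window_regions = nrow(unique(zone_calls[, c("exon_id", "zone")])),
       n_exon_regions = length(unique(zone_calls$exon_id)))
}
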