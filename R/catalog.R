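#' Find (weak AFE, strong SE) pairs within one gene
#'
#' Emits every combination of a weak alternative first exon and a strong
#' skipped exon satisfying the EMATS structural criteria: the two exons
#' do not overlap, the wAFE 5' coordinate is transcriptionally upstream
#' of the sSE 5' coordinate, and the strand-aware distance between the
#' two 5' coordinates is at most `max_distance` (inclusive).
#'
#' @param weak_afes meta-exon rows called weak, class AFE (may carry a
#'   `median_psi` column).
#' @param strong_ses meta-exon rows called strong, class SE.
#' @param max_distance maximum 5'-to-5' distance in nt (default 5000).
#' @return data.frame of pairs: `pair_id`, `gene_id`, `chrom`, `strand`,
#'   wAFE and sSE ids/coordinates/median PSIs, and `distance_5p`.
#' @export
find_emats_pairs <- function(weak_afes, strong_ses, max_distance = 5000) {
  empty <- data.frame(pair_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      wafe_id = character(), wafe_start = integer(),
                      wafe_end = integer(), wafe_median_psi = numeric(),
                      sse_id = character(), sse_start = integer(),
                      sse_end = integer(), sse_median_psi = numeric(),
                      distance_5p = integer(), stringsAsFactors = FALSE)
  if (is.null(weak_afes) || is.null(strong_ses) ||
      nrow(weak_afes) == 0L || nrow(strong_ses) == 0L) return(empty)
  gid <- unique(c(weak_afes$gene_id, strong_ses$gene_id))
  if (length(gid) != 1L)
    stop("find_emats_pairs expects exons of a single gene; got: ",
         paste(gid, collapse = ", "))
  idx <- expand.grid(w = seq_len(nrow(weak_afes)), s = seq_len(nrow(strong_ses)))
  w <- weak_afes[idx$w, , drop = FALSE]
  s <- strong_ses[idx$s, , drop = FALSE]
  w5 <- five_prime(w$start, w$end, w$strand)
  s5 <- five_prime(s$start, s$end, s$strand)
  no_overlap <- w$end <= s$start | s$end <= w$start
  upstream <- tx_pos(w5, w$strand) < tx_pos(s5, s$strand)
  dist <- abs(s5 - w5)
  keep <- no_overlap & upstream & dist <= max_distance
  if (!any(keep)) return(empty)
  out <- data.frame(
    pair_id = NA_character_, gene_id = gid,
    chrom = w$chrom[keep], strand = w$strand[keep],
    wafe_id = w$exon_id[keep], wafe_start = w$start[keep], wafe_end = w$end[keep],
    wafe_median_psi = if (is.null(w$median_psi)) NA_real_ else w$median_psi[keep],
    sse_id = s$exon_id[keep], sse_start = s$start[keep], sse_end = s$end[keep],
    sse_median_psi = if (is.null(s$median_psi)) NA_real_ else s$median_psi[keep],
    distance_5p = as.integer(dist[keep]), stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("gene_id", "wafe_start", "wafe_end",
                                 "sse_start", "sse_end")]), , drop = FALSE]
  out$pair_id <- paste0(gid, ":P", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

is_afe_candidate <- function(meta) {
  meta$role == "first" | (meta$role == "hybrid" & !is.na(meta$hit) & meta$hit > 0)
}

#' Build an EMATS catalog from classified exons and strength calls
#'
#' Applies the identification cascade: protein-coding genes -> genes with
#' a skipped exon -> genes with at least two alternative first exons ->
#' weak/strong strength calls relative to the classification-wide median
#' -> structural pairing of weak AFEs with strong SEs within
#' `max_distance`. Pairs are deduplicated by (gene, wAFE interval, sSE
#' interval).
#'
#' @param genes the `genes` data.frame of an `emats_annotation` (already
#'   biotype-filtered).
#' @param meta classified meta-exons ([classify_exons()] output).
#' @param afe_median,se_median named across-tissue median PSI vectors for
#'   the AFE and SE event classes (names are `exon_id`s).
#' @param scope label, `"inter-tissue"` or `"tissue:<name>"`.
#' @param max_distance maximum wAFE-to-sSE 5' distance in nt.
#' @return an `emats_catalog`: list with `scope`, `pairs`, `genes`
#'   (character vector of EMATS gene IDs), `events` (AFE/SE event tables
#'   with calls), `cascade` (named integer counts), `max_distance`.
#' @export
build_catalog <- function(genes, meta, afe_median, se_median,
                          scope = "inter-tissue", max_distance = 5000) {
  unknown <- setdiff(c(names(afe_median), names(se_median)), meta$exon_id)
  if (length(unknown))
    stop("strength call references unknown event: ", unknown[1])

  afe_ev <- meta[meta$exon_id %in% names(afe_median) & is_afe_candidate(meta) &
                 meta$is_alternative, , drop = FALSE]
  afe_ev$median_psi <- unname(afe_median[afe_ev$exon_id])
  afe_ev <- afe_ev[!is.na(afe_ev$median_psi), , drop = FALSE]
  se_ev <- meta[meta$exon_id %in% names(se_median) & meta$role == "internal" &
                meta$is_alternative, , drop = FALSE]
  se_ev$median_psi <- unname(se_median[se_ev$exon_id])
  se_ev <- se_ev[!is.na(se_ev$median_psi), , drop = FALSE]

  afe_ev$call <- if (nrow(afe_ev)) unname(
    call_strength(stats::setNames(afe_ev$median_psi, afe_ev$exon_id))) else character(0)
  se_ev$call <- if (nrow(se_ev)) unname(
    call_strength(stats::setNames(se_ev$median_psi, se_ev$exon_id))) else character(0)

  g_all <- genes$gene_id
  g_se <- intersect(g_all, unique(se_ev$gene_id))
  afe_n <- table(afe_ev$gene_id)
  g_2afe <- intersect(g_se, names(afe_n)[afe_n >= 2])
  g_wafe <- intersect(g_2afe, unique(afe_ev$gene_id[afe_ev$call == "weak"]))
  g_sse <- intersect(g_wafe, unique(se_ev$gene_id[se_ev$call == "strong"]))

  pair_list <- lapply(g_sse, function(g) {
    find_emats_pairs(afe_ev[afe_ev$gene_id == g & afe_ev$call == "weak", , drop = FALSE],
                     se_ev[se_ev$gene_id == g & se_ev$call == "strong", , drop = FALSE],
                     max_distance)
  })
  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    find_emats_pairs(NULL, NULL)
  rownames(pairs) <- NULL
  emats_genes <- sort(unique(pairs$gene_id))
  cascade <- c(genes = length(g_all), with_se = length(g_se),
               with_2afe = length(g_2afe), with_wafe = length(g_wafe),
               with_sse = length(g_sse), emats_genes = length(emats_genes),
               pairs = nrow(pairs))
  structure(list(scope = scope, pairs = pairs, genes = emats_genes,
                 events = list(afe = afe_ev, se = se_ev),
                 cascade = cascade, max_distance = max_distance),
            class = "emats_catalog")
}

#' @export
print.emats_catalog <- function(x, ...) {
  cat("EMATS catalog [", x$scope, "]\n", sep = "")
  cat("  identification cascade:\n")
  lab <- c(genes = "genes in", with_se = "with skipped exon",
           with_2afe = "with >=2 alternative first exons",
           with_wafe = "with weak AFE", with_sse = "with strong SE",
           emats_genes = "EMATS genes", pairs = "wAFE/sSE pairs")
  for (k in names(x$cascade))
    cat(sprintf("    %-34s %d\n", lab[[k]], x$cascade[[k]]))
  invisible(x)
}

#' Scan an annotated dataset for EMATS genes
#'
#' The package's central entry point: collapses the annotation into
#' meta-exons, classifies exon roles from the pooled splice-junction-read
#' imbalance, quantifies first-exon usage and skipped-exon PSI per
#' sample, aggregates to across-tissue medians, calls weak/strong events
#' against the classification-wide medians, and applies the three EMATS
#' criteria both across tissues and per tissue.
#'
#' @param annotation an `emats_annotation` or a GTF/GFF path.
#' @param junctions a junction count data.frame or TSV path
#'   (see [read_junctions()]).
#' @param sample_map a data.frame (`sample_id`, `tissue`, optional
#'   `group`) or TSV path.
#' @param max_distance maximum wAFE-to-sSE 5'-to-5' distance (nt).
#' @param t_terminal,t_internal,min_reads exon-role thresholds
#'   (see [classify_exon()]).
#' @param per_tissue also build one catalog per tissue (needed for
#'   tissue-specific calls and the overlap matrix).
#' @param aggregate across-tissue aggregation rule (see [median_psi()]).
#' @param gene_type_filter biotype filter applied when `annotation` is a
#'   path.
#' @return an `emats_scan` object: list with `annotation`, `meta`
#'   (classified meta-exons), `psi` (AFE and SE per-sample matrices),
#'   `median_psi`, `catalog` (inter-tissue `emats_catalog`),
#'   `per_tissue` (named list of per-tissue catalogs or NULL),
#'   `sample_map`, and `params`.
#' @export
emats_scan <- function(annotation, junctions, sample_map,
                       max_distance = 5000, t_terminal = 0.8,
                       t_internal = 0.2, min_reads = 10,
                       per_tissue = TRUE,
                       aggregate = c("mean_then_median", "pooled_median"),
                       gene_type_filter = "protein_coding") {
  aggregate <- match.arg(aggregate)
  if (is.character(annotation)) {
    annotation <- parse_annotation(annotation, gene_type_filter)
  } else if (!is.null(gene_type_filter) && !is.null(annotation$genes$gene_type)) {
    keep <- annotation$genes$gene_id[!is.na(annotation$genes$gene_type) &
                                     annotation$genes$gene_type == gene_type_filter]
    annotation$genes <- annotation$genes[annotation$genes$gene_id %in% keep, , drop = FALSE]
    annotation$exons <- annotation$exons[annotation$exons$gene_id %in% keep, , drop = FALSE]
  }
  if (is.character(junctions)) junctions <- read_junctions(junctions)
  if (is.character(sample_map)) sample_map <- read_sample_map(sample_map)
  if (is.null(sample_map$group)) sample_map$group <- sample_map$tissue

  meta <- collapse_meta_exons(annotation)
  meta <- classify_exons(meta, junctions, t_terminal, t_internal, min_reads)
  samples <- sort(unique(junctions$sample_id))

  firsts <- meta[is_afe_candidate(meta), , drop = FALSE]
  afe_mx <- if (nrow(firsts)) afe_psi(firsts, junctions, samples) else
    matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples))
  internals <- meta[meta$role == "internal" & meta$is_alternative, , drop = FALSE]
  se_mx <- se_psi_matrix(internals, junctions, samples)

  afe_event_rows <- rownames(afe_mx)[rownames(afe_mx) %in%
                                     meta$exon_id[meta$is_alternative]]
  afe_ev_mx <- afe_mx[afe_event_rows, , drop = FALSE]

  med <- function(mx, sm) {
    if (nrow(mx) == 0L) return(stats::setNames(numeric(0), character(0)))
    keep <- intersect(colnames(mx), sm$sample_id)
    median_psi(mx[, keep, drop = FALSE], sm, aggregate)
  }
  afe_med <- med(afe_ev_mx, sample_map)
  se_med <- med(se_mx, sample_map)
  catalog <- build_catalog(annotation$genes, meta, afe_med, se_med,
                           "inter-tissue", max_distance)

  per_tissue_catalogs <- NULL
  if (per_tissue) {
    tissues <- sort(unique(sample_map$tissue))
    per_tissue_catalogs <- lapply(tissues, function(tt) {
      sm <- sample_map[sample_map$tissue == tt, , drop = FALSE]
      build_catalog(annotation$genes, meta,
                    med(afe_ev_mx, sm), med(se_mx, sm),
                    paste0("tissue:", tt), max_distance)
    })
    names(per_tissue_catalogs) <- tissues
  }
  structure(list(annotation = annotation, meta = meta,
                 psi = list(afe = afe_mx, se = se_mx),
                 median_psi = list(afe = afe_med, se = se_med),
                 catalog = catalog, per_tissue = per_tissue_catalogs,
                 sample_map = sample_map,
                 params = list(max_distance = max_distance,
                               t_terminal = t_terminal,
                               t_internal = t_internal,
                               min_reads = min_reads,
                               aggregate = aggregate)),
            class = "emats_scan")
}

#' @export
print.emats_scan <- function(x, ...) {
  cat("emats_scan:", nrow(x$annotation$genes), "genes,",
      nrow(x$meta), "meta-exons,",
      length(unique(x$sample_map$tissue)), "tissues\n")
  print(x$catalog)
  if (!is.null(x$per_tissue))
    cat("  per-tissue catalogs:", length(x$per_tissue), "\n")
  invisible(x)
}

#' @export
summary.emats_scan <- function(object, ...) {
  arch <- summarize_architecture(object$catalog, object$annotation, object$meta)
  out <- list(cascade = object$catalog$cascade,
              n_emats = length(object$catalog$genes),
              n_pairs = nrow(object$catalog$pairs),
              architecture = arch,
              tissue_specific = if (!is.null(object$per_tissue))
                call_tissue_specific(object$per_tissue,
                                     grouping_from_map(object$sample_map)) else NULL)
  class(out) <- "summary.emats_scan"
  out
}

#' @export
print.summary.emats_scan <- function(x, ...) {
  cat("EMATS scan summary\n")
  cat("  EMATS genes:", x$n_emats, " pairs:", x$n_pairs, "\n")
  cat(sprintf("  mean gene length: EMATS %.1f kb vs other %.1f kb (t-test p = %.3g)\n",
              x$architecture$mean_length_emats, x$architecture$mean_length_other,
              x$architecture$length_test$p.value))
  cat(sprintf("  catalog AFE roles: %.1f%% obligate first, %.1f%% hybrid\n",
              x$architecture$pct_fe, x$architecture$pct_hfe))
  if (!is.null(x$tissue_specific)) {
    n <- sum(lengths(x$tissue_specific))
    cat("  tissue-specific EMATS genes:", n, "across",
        length(x$tissue_specific), "tissue groups\n")
  }
  invisible(x)
}

grouping_from_map <- function(sample_map) {
  g <- unique(sample_map[, c("tissue", "group")])
  stats::setNames(g$group, g$tissue)
}

#' Call tissue-specific EMATS genes
#'
#' A gene is specific to a tissue (or tissue group) when it is identified
#' in that tissue and in no tissue outside the group; sub-types of one
#' group may share the gene, e.g. a brain-specific gene may appear in
#' several brain sub-types but nowhere else.
#'
#' @param per_tissue_catalogs named list of `emats_catalog` objects (or
#'   plain character vectors of gene IDs), one per tissue.
#' @param grouping named character vector mapping tissue -> group;
#'   default: every tissue is its own group. Every name must be a tissue
#'   present in `per_tissue_catalogs`.
#' @return named list: tissue group -> character vector of specific genes.
#' @export
call_tissue_specific <- function(per_tissue_catalogs, grouping = NULL) {
  if (length(per_tissue_catalogs) < 2L)
    stop("tissue-specific calling needs at least 2 tissues")
  sets <- lapply(per_tissue_catalogs, function(x)
    if (inherits(x, "emats_catalog")) x$genes else as.character(x))
  tissues <- names(sets)
  if (is.null(grouping)) grouping <- stats::setNames(tissues, tissues)
  unknown <- setdiff(names(grouping), tissues)
  if (length(unknown)) stop("unknown tissue in grouping map: ", unknown[1])
  grp <- unname(grouping[tissues])
  if (any(is.na(grp))) stop("grouping map lacks tissues: ",
                            tissues[is.na(grp)][1])
  out <- lapply(unique(grp), function(g) {
    inside <- unique(unlist(sets[grp == g], use.names = FALSE))
    outside <- unique(unlist(sets[grp != g], use.names = FALSE))
    sort(setdiff(inside, outside))
  })
  stats::setNames(out, unique(grp))
}

#' Jaccard overlap between per-tissue EMATS gene sets
#'
#' @inheritParams call_tissue_specific
#' @return symmetric matrix of Jaccard indices in `[0, 1]`; the diagonal
#'   is 1 for non-empty sets (0 for empty ones).
#' @export
tissue_overlap_matrix <- function(per_tissue_catalogs) {
  sets <- lapply(per_tissue_catalogs, function(x)
    if (inherits(x, "emats_catalog")) x$genes else as.character(x))
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- length(union(sets[[i]], sets[[j]]))
    m[i, j] <- if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
  }
  m
}

#' Architecture summary of an EMATS catalog
#'
#' Computes per-gene length in kilobases with an EMATS / non-EMATS
#' two-sided independent (Welch) t-test, the split of catalog wAFEs into
#' obligate first exons (FE) versus hybrid first exons (HFE), and the
#' distance of every catalog exon to its host gene's 5' coordinate (plus
#' the same distance relative to gene length).
#'
#' @param catalog an `emats_catalog`.
#' @param annotation the `emats_annotation` the catalog was built from.
#' @param meta classified meta-exons (for exon roles).
#' @return list with `gene_lengths` (data.frame `gene_id`, `length_kb`,
#'   `is_emats`), `length_test` (htest or NULL), `mean_length_emats`,
#'   `mean_length_other`, `pct_fe`, `pct_hfe`, `positions` (data.frame of
#'   per-exon distances with exon class FE/HFE/SE).
#' @export
summarize_architecture <- function(catalog, annotation, meta) {
  g <- annotation$genes
  gl <- data.frame(gene_id = g$gene_id,
                   length_kb = gene_length_kb(g$start, g$end),
                   is_emats = g$gene_id %in% catalog$genes,
                   stringsAsFactors = FALSE)
  tt <- NULL
  if (sum(gl$is_emats) >= 2L && sum(!gl$is_emats) >= 2L)
    tt <- stats::t.test(gl$length_kb[gl$is_emats], gl$length_kb[!gl$is_emats],
                        alternative = "two.sided", var.equal = FALSE)
  # first exons "in an EMATS structure": every AFE event of a catalog gene
  afe_ids <- unique(catalog$events$afe$exon_id[
    catalog$events$afe$gene_id %in% catalog$genes])
  roles <- meta$role[match(afe_ids, meta$exon_id)]
  n_fe <- sum(roles == "first"); n_hfe <- sum(roles == "hybrid")
  pct_fe <- if (length(afe_ids)) 100 * n_fe / length(afe_ids) else NA_real_
  pct_hfe <- if (length(afe_ids)) 100 * n_hfe / length(afe_ids) else NA_real_

  pos <- NULL
  if (nrow(catalog$pairs)) {
    ids <- unique(c(afe_ids, catalog$pairs$sse_id))
    mm <- meta[match(ids, meta$exon_id), , drop = FALSE]
    gg <- g[match(mm$gene_id, g$gene_id), , drop = FALSE]
    cls <- ifelse(ids %in% catalog$pairs$sse_id, "SE",
                  ifelse(mm$role == "hybrid", "HFE", "FE"))
    d <- exon_distance_to_gene_5prime(mm$start, mm$end, gg$start, gg$end, gg$strand)
    pos <- data.frame(exon_id = ids, gene_id = mm$gene_id, class = cls,
                      dist_to_5p = d,
                      rel_position = d / (gg$end - gg$start),
                      stringsAsFactors = FALSE)
  }
  list(gene_lengths = gl, length_test = tt,
       mean_length_emats = mean(gl$length_kb[gl$is_emats]),
       mean_length_other = mean(gl$length_kb[!gl$is_emats]),
       pct_fe = pct_fe, pct_hfe = pct_hfe, positions = pos)
}
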