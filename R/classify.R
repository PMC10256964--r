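#' Splice-junction-read profile of an exon
#'
#' For a meta-exon, `n_up` is the summed count of junctions whose
#' transcription-direction acceptor coincides with the exon's 5' boundary
#' (reads spliced *into* the exon) and `n_down` the summed count of
#' junctions whose donor coincides with the exon's 3' boundary (reads
#' spliced *out of* it). The downstream imbalance
#' `hit = (n_down - n_up) / (n_down + n_up)` is +1 for a pure first-exon
#' profile, 0 for a balanced internal profile and -1 for a pure last-exon
#' profile; it is undefined (NA) when the exon has no junction coverage.
#'
#' @param exon one meta-exon row (`chrom`, `start`, `end`, `strand`).
#' @param junctions junction count data.frame (see [read_junctions()]).
#' @param sample restrict to one `sample_id`; `NULL` pools all samples.
#' @return list with `n_up`, `n_down`, `hit`.
#' @export
sjr_profile <- function(exon, junctions, sample = NULL) {
  if (!is.null(sample)) junctions <- junctions[junctions$sample_id == sample, , drop = FALSE]
  j <- junctions[junctions$chrom == exon$chrom & junctions$strand == exon$strand, , drop = FALSE]
  fp <- five_prime(exon$start, exon$end, exon$strand)
  tp <- three_prime(exon$start, exon$end, exon$strand)
  n_up <- sum(j$count[j$acceptor == fp])
  n_down <- sum(j$count[j$donor == tp])
  list(n_up = n_up, n_down = n_down, hit = hit_index(n_up, n_down))
}

hit_index <- function(n_up, n_down) {
  tot <- n_up + n_down
  ifelse(tot > 0, (n_down - n_up) / tot, NA_real_)
}

#' Classify an exon's role from its pooled junction profile
#'
#' Applies the downstream splice-junction-read imbalance rule: pooled
#' `hit >= t_terminal` is a first exon, `hit <= -t_terminal` a last exon,
#' `|hit| <= t_internal` internal, anything between the thresholds hybrid
#' (positive side: hybrid first/internal). Exons with fewer than
#' `min_reads` pooled junction reads stay unclassified. Only annotated
#' meta-exons are ever presented to this rule.
#'
#' @param n_up,n_down pooled junction read counts (vectors allowed).
#' @param t_terminal,t_internal imbalance thresholds, `t_terminal > t_internal > 0`.
#' @param min_reads minimum pooled `n_up + n_down`.
#' @return character vector of roles in
#'   `c("first", "internal", "last", "hybrid", "unclassified")`.
#' @export
classify_exon <- function(n_up, n_down, t_terminal = 0.8, t_internal = 0.2,
                          min_reads = 10) {
  if (!(t_terminal > t_internal && t_internal > 0))
    stop("thresholds must satisfy t_terminal > t_internal > 0")
  h <- hit_index(n_up, n_down)
  role <- rep("unclassified", length(h))
  ok <- !is.na(h) & (n_up + n_down) >= min_reads
  role[ok & h >= t_terminal] <- "first"
  role[ok & h <= -t_terminal] <- "last"
  role[ok & abs(h) <= t_internal] <- "internal"
  role[ok & role == "unclassified"] <- "hybrid"
  role
}

#' Classify every meta-exon of an annotation from pooled junction reads
#'
#' @param meta meta-exon data.frame from [collapse_meta_exons()].
#' @param junctions junction count data.frame.
#' @inheritParams classify_exon
#' @return `meta` with added columns `n_up`, `n_down`, `hit`, `role`.
#' @export
classify_exons <- function(meta, junctions, t_terminal = 0.8,
                           t_internal = 0.2, min_reads = 10) {
  acc <- junction_boundary_sums(junctions, "acceptor")
  don <- junction_boundary_sums(junctions, "donor")
  fp_key <- boundary_key(meta$chrom, meta$strand,
                         five_prime(meta$start, meta$end, meta$strand))
  tp_key <- boundary_key(meta$chrom, meta$strand,
                         three_prime(meta$start, meta$end, meta$strand))
  meta$n_up <- unname(ifelse(fp_key %in% names(acc), acc[fp_key], 0))
  meta$n_down <- unname(ifelse(tp_key %in% names(don), don[tp_key], 0))
  meta$hit <- hit_index(meta$n_up, meta$n_down)
  meta$role <- classify_exon(meta$n_up, meta$n_down, t_terminal, t_internal,
                             min_reads)
  meta
}

# as.integer: doubles like 5e5 would otherwise render in scientific
# notation and never match their integer counterparts
boundary_key <- function(chrom, strand, coord)
  paste(chrom, strand, as.integer(round(coord)), sep = ":")

junction_boundary_sums <- function(jx, side) {
  key <- boundary_key(jx$chrom, jx$strand, jx[[side]])
  v <- rowsum(jx$count, key)
  stats::setNames(as.numeric(v), rownames(v))
}

# boundary x sample count matrix (rows keyed by boundary)
junction_sample_matrix <- function(jx, side, samples) {
  key <- boundary_key(jx$chrom, jx$strand, jx[[side]])
  m <- tapply(jx$count, list(factor(key), factor(jx$sample_id, levels = samples)),
              sum, default = 0)
  m[is.na(m)] <- 0
  m
}

#' Per-sample alternative-first-exon PSI
#'
#' First-exon usage: for each sample, an AFE's PSI is its share of the
#' downstream splice-junction reads summed over the gene's first
#' (including hybrid-first) exons. Values sum to 1 over a gene's first
#' exons whenever the gene has any first-exon coverage in the sample, and
#' are missing (never 0) when it has none.
#'
#' @param first_exons meta-exon rows of one or more genes whose role is
#'   first or hybrid-first (classified via [classify_exons()]).
#' @param junctions junction count data.frame.
#' @param samples sample IDs defining matrix columns; default all in
#'   `junctions`.
#' @return numeric matrix, rows = `first_exons$exon_id`, cols = samples.
#' @export
afe_psi <- function(first_exons, junctions, samples = NULL) {
  if (nrow(first_exons) == 0L) stop("no first exons supplied")
  if (is.null(samples)) samples <- sort(unique(junctions$sample_id))
  don <- junction_sample_matrix(junctions, "donor", samples)
  tp_key <- boundary_key(first_exons$chrom, first_exons$strand,
                         three_prime(first_exons$start, first_exons$end,
                                     first_exons$strand))
  nd <- matrix(0, nrow(first_exons), length(samples),
               dimnames = list(first_exons$exon_id, samples))
  hitrows <- tp_key %in% rownames(don)
  nd[hitrows, ] <- don[tp_key[hitrows], , drop = FALSE]
  psi <- nd
  for (g in unique(first_exons$gene_id)) {
    rows <- which(first_exons$gene_id == g)
    tot <- colSums(nd[rows, , drop = FALSE])
    denom <- rep(tot, each = length(rows))
    block <- nd[rows, , drop = FALSE] / matrix(denom, nrow = length(rows))
    block[, tot == 0] <- NA_real_
    psi[rows, ] <- block
  }
  psi
}

#' Skipped-exon PSI from junction counts
#'
#' With inclusion reads `I = inclusion_up + inclusion_down` (junctions
#' into the exon's 5' boundary and out of its 3' boundary) and `skip`
#' reads spanning the exon, `PSI = (I/2) / ((I/2) + skip)`: inclusion is
#' supported by two junctions and skipping by one, so inclusion counts
#' are halved. Undefined (NA) when `I + skip = 0`.
#'
#' @param inclusion_up,inclusion_down,skip non-negative junction read counts.
#' @return PSI in `[0, 1]` or NA.
#' @examples
#' se_psi(6, 6, 3)  # 0.667
#' @export
se_psi <- function(inclusion_up, inclusion_down, skip) {
  if (any(c(inclusion_up, inclusion_down, skip) < 0))
    stop("junction counts must be non-negative")
  inc <- (inclusion_up + inclusion_down) / 2
  ifelse(inc + skip > 0, inc / (inc + skip), NA_real_)
}

#' Per-sample skipped-exon PSI for internal meta-exons
#'
#' Inclusion reads are the junctions ending at the exon's 5' boundary and
#' starting at its 3' boundary; skip reads are junctions whose intron
#' fully contains the exon.
#'
#' @param internal_exons meta-exon rows (typically role internal,
#'   alternative).
#' @param junctions junction count data.frame.
#' @param samples sample IDs defining matrix columns.
#' @return numeric matrix, rows = `internal_exons$exon_id`, cols = samples.
#' @export
se_psi_matrix <- function(internal_exons, junctions, samples = NULL) {
  if (nrow(internal_exons) == 0L)
    return(matrix(numeric(0), 0, 0))
  if (is.null(samples)) samples <- sort(unique(junctions$sample_id))
  acc <- junction_sample_matrix(junctions, "acceptor", samples)
  don <- junction_sample_matrix(junctions, "donor", samples)
  fp_key <- boundary_key(internal_exons$chrom, internal_exons$strand,
                         five_prime(internal_exons$start, internal_exons$end,
                                    internal_exons$strand))
  tp_key <- boundary_key(internal_exons$chrom, internal_exons$strand,
                         three_prime(internal_exons$start, internal_exons$end,
                                     internal_exons$strand))
  pick <- function(m, keys) {
    out <- matrix(0, length(keys), length(samples),
                  dimnames = list(internal_exons$exon_id, samples))
    hit <- keys %in% rownames(m)
    out[hit, ] <- m[keys[hit], , drop = FALSE]
    out
  }
  inc_up <- pick(acc, fp_key)
  inc_down <- pick(don, tp_key)
  skip <- skip_count_matrix(internal_exons, junctions, samples)
  inc <- (inc_up + inc_down) / 2
  psi <- inc / (inc + skip)
  psi[inc + skip == 0] <- NA_real_
  psi
}

# exon x sample matrix of junction reads whose intron fully contains the exon
skip_count_matrix <- function(exons, jx, samples) {
  out <- matrix(0, nrow(exons), length(samples),
                dimnames = list(exons$exon_id, samples))
  lo <- pmin(jx$donor, jx$acceptor)
  hi <- pmax(jx$donor, jx$acceptor)
  grp_j <- paste(jx$chrom, jx$strand)
  grp_e <- paste(exons$chrom, exons$strand)
  for (g in unique(grp_e)) {
    ei <- which(grp_e == g)
    ji <- which(grp_j == g)
    if (!length(ji)) next
    ir_e <- IRanges::IRanges(exons$start[ei] + 1L, exons$end[ei])
    ir_j <- IRanges::IRanges(lo[ji] + 1L, hi[ji])
    ov <- IRanges::findOverlaps(ir_e, ir_j, type = "within")
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    sj <- factor(jx$sample_id[ji][si], levels = samples)
    agg <- tapply(jx$count[ji][si], list(factor(qi, levels = seq_along(ei)), sj),
                  sum, default = 0)
    agg[is.na(agg)] <- 0
    out[ei, ] <- out[ei, ] + agg
  }
  out
}

#' Median PSI across tissues
#'
#' Aggregates per-sample PSI to a single per-event value the way the
#' catalog criteria require: mean of the defined per-sample values within
#' each tissue, then the median over tissues having at least one defined
#' value. Missing values propagate as missing, never as 0.
#'
#' @param psi numeric vector (one event, named by sample) or matrix
#'   (events x samples).
#' @param sample_map data.frame `sample_id`, `tissue`.
#' @param aggregate `"mean_then_median"` (default) or `"pooled_median"`
#'   (plain median over all samples, ignoring tissue structure).
#' @return numeric vector of per-event median PSI (NA when nothing is
#'   defined).
#' @export
median_psi <- function(psi, sample_map, aggregate = c("mean_then_median", "pooled_median")) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(psi))) psi <- matrix(psi, 1, dimnames = list("event", names(psi)))
  tissues <- sample_map$tissue[match(colnames(psi), sample_map$sample_id)]
  if (any(is.na(tissues))) stop("samples missing from the sample map: ",
                                paste(colnames(psi)[is.na(tissues)][1], "..."))
  if (aggregate == "pooled_median")
    return(apply(psi, 1, function(x) stats::median(x, na.rm = TRUE)))
  out <- apply(psi, 1, function(x) {
    m <- tapply(x, tissues, function(v) mean(v, na.rm = TRUE))
    m <- m[!is.nan(m) & !is.na(m)]
    if (!length(m)) NA_real_ else stats::median(m)
  })
  out
}

#' Call weak / strong splicing events within one event class
#'
#' The classification-wide threshold is the median of all events'
#' across-tissue median PSI within the class (AFE or SE). Events strictly
#' below the threshold are weak, strictly above strong, and exactly at
#' the threshold neither.
#'
#' @param median_psi named numeric vector of per-event median PSI for one
#'   event class (NAs dropped).
#' @return named character vector `"weak"` / `"strong"` / `"neither"`.
#' @examples
#' call_strength(c(a = 0.1, b = 0.4, c = 0.9))
#' @export
call_strength <- function(median_psi) {
  median_psi <- median_psi[!is.na(median_psi)]
  if (length(median_psi) < 1L) stop("empty event class")
  thr <- stats::median(median_psi)
  out <- rep("neither", length(median_psi))
  out[median_psi < thr] <- "weak"
  out[median_psi > thr] <- "strong"
  stats::setNames(out, names(median_psi))
}
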