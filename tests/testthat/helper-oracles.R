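# Independent oracles and small fixture builders shared across tests.

# Per-base boolean-coverage union of 0-based half-open intervals:
# the brute-force reference for meta-exon collapsing.
oracle_union <- function(start, end) {
  lim <- max(end)
  cov <- logical(lim)
  for (i in seq_along(start)) cov[(start[i] + 1L):end[i]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values] - 1L, end = ends[r$values])
}

# Rank-then-Pearson Spearman oracle, written out from the product-moment
# formula (independent of stats::cor).
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Brute-force EMATS pair enumeration over all (weak AFE, strong SE)
# combinations of one gene, checking each criterion explicitly.
oracle_pairs <- function(wafes, sses, max_distance = 5000) {
  out <- list()
  for (i in seq_len(nrow(wafes))) for (j in seq_len(nrow(sses))) {
    w <- wafes[i, ]; s <- sses[j, ]
    w5 <- if (w$strand == "+") w$start else w$end
    s5 <- if (s$strand == "+") s$start else s$end
    overlap <- w$start < s$end && s$start < w$end
    upstream <- if (w$strand == "+") w5 < s5 else w5 > s5
    if (!overlap && upstream && abs(s5 - w5) <= max_distance)
      out[[length(out) + 1L]] <- c(i, j, abs(s5 - w5))
  }
  if (!length(out)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, out)
}

# Exon table builder for classification unit tests.
make_exons <- function(gene_id, chrom, strand, tx) {
  do.call(rbind, lapply(names(tx), function(t)
    data.frame(gene_id = gene_id, transcript_id = t, chrom = chrom,
               start = tx[[t]][, 1], end = tx[[t]][, 2], strand = strand,
               stringsAsFactors = FALSE)))
}

# A small two-gene GTF (one protein-coding, one lncRNA) on disk.
write_toy_gtf <- function(path) {
  lines <- c(
    'chr1\ttoy\tgene\t1001\t9000\t.\t+\t.\tgene_id "PC1"; gene_type "protein_coding";',
    'chr1\ttoy\texon\t1001\t1200\t.\t+\t.\tgene_id "PC1"; transcript_id "PC1.t1"; gene_type "protein_coding";',
    'chr1\ttoy\texon\t3001\t3100\t.\t+\t.\tgene_id "PC1"; transcript_id "PC1.t1"; gene_type "protein_coding";',
    'chr1\ttoy\texon\t8001\t9000\t.\t+\t.\tgene_id "PC1"; transcript_id "PC1.t1"; gene_type "protein_coding";',
    'chr1\ttoy\texon\t1001\t1200\t.\t+\t.\tgene_id "PC1"; transcript_id "PC1.t2"; gene_type "protein_coding";',
    'chr1\ttoy\texon\t8001\t9000\t.\t+\t.\tgene_id "PC1"; transcript_id "PC1.t2"; gene_type "protein_coding";',
    'chr2\ttoy\tgene\t501\t2000\t.\t-\t.\tgene_id "NC1"; gene_type "lncRNA";',
    'chr2\ttoy\texon\t501\t700\t.\t-\t.\tgene_id "NC1"; transcript_id "NC1.t1"; gene_type "lncRNA";',
    'chr2\ttoy\texon\t1801\t2000\t.\t-\t.\tgene_id "NC1"; transcript_id "NC1.t1"; gene_type "lncRNA";')
  writeLines(lines, path)
  path
}

# Random interval set without exact bookends (end of one == start of
# another). A per-base coverage oracle cannot represent the half-open
# boundary-only distinction, so bookend behaviour has its own unit test
# and the oracle comparison runs on bookend-free sets.
random_interval_set <- function(max_n = 50, max_coord = 1e5, max_len = 500) {
  repeat {
    n <- sample(seq_len(max_n), 1)
    start <- sample.int(max_coord - max_len - 1L, n)
    end <- start + sample.int(max_len, n, replace = TRUE)
    if (!any(end %in% start)) return(data.frame(start = start, end = end))
  }
}

# Mean absolute error of the junction-based skipped-exon PSI estimator
# against the planted per-tissue truth, at a given sequencing depth.
sim_se_psi_mae <- function(depth, seed = 99, n_genes = 30) {
  cfg <- emats_sim_config(seed = seed, n_genes = n_genes, n_tissues = 2,
                          samples_per_tissue = 5, depth_mean = depth)
  sim <- emats_simulate(cfg)
  meta <- collapse_meta_exons(sim$annotation)
  meta <- classify_exons(meta, sim$junctions)
  internals <- meta[meta$role == "internal" & meta$is_alternative, ]
  psi <- se_psi_matrix(internals, sim$junctions)
  sm <- sim$sample_map
  errs <- c()
  for (i in seq_len(nrow(internals))) {
    g <- internals$gene_id[i]
    tp <- sim$truth$psi[sim$truth$psi$gene_id == g, ]
    exg <- sim$truth$exons[sim$truth$exons$gene_id == g, ]
    nm <- exg$exon[match(internals$start[i], exg$start)]
    if (!nm %in% c("SEf", "SEb")) next
    true_col <- if (nm == "SEf") "psi_se_focal" else "psi_se_bal"
    tv <- tp[[true_col]][match(sm$tissue, tp$tissue)]
    errs <- c(errs, abs(psi[i, sm$sample_id] - tv))
  }
  mean(errs, na.rm = TRUE)
}

# Shared small simulation (cached per session) for tests that only read it.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- emats_simulate(emats_sim_config(seed = 42, n_genes = 40,
                                                n_tissues = 3,
                                                samples_per_tissue = 8))
    cache
  }
})
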