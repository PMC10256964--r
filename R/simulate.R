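#' Configuration for the synthetic EMATS data generator
#'
#' The generator plants a known EMATS structure in a fraction of genes
#' and makes every non-EMATS gene violate one criterion: `"dist"` (weak
#' AFE more than 5 kb from the strong SE), `"strong_afe"` (the only AFE
#' within pairing range of the strong SE is the strong one; the weak AFE
#' sits just beyond 5 kb), `"weak_se"` (the proximal skipped exon is
#' weakly included), `"single_afe"` (one constitutive first exon),
#' assigned round-robin. Per-tissue true PSI values are drawn from Beta
#' distributions truncated to (0, `psi_weak_max`] for weak events and
#' [`psi_strong_min`, 1) for strong events, so weak and strong events
#' straddle the classification-wide median by construction. Every gene
#' additionally carries a far-downstream alternative internal exon of
#' the opposite strength (outside pairing range) so the skipped-exon
#' class stays balanced around its median.
#'
#' @param seed integer master seed; every output flows from it through
#'   named sub-streams, one per file type.
#' @param n_genes number of protein-coding genes.
#' @param frac_emats fraction of genes with a planted EMATS pair.
#' @param n_tissues,samples_per_tissue cohort shape.
#' @param depth_mean mean junction depth per gene per sample (Poisson).
#' @param psi_afe_weak,psi_se_strong Beta shape pairs for weak AFE and
#'   strong SE true PSI.
#' @param psi_weak_max,psi_strong_min truncation bounds separating the
#'   weak and strong PSI clusters.
#' @param coupling list `beta0`, `beta1_emats`, `beta1_other`, `sigma`
#'   for `log2 TPM = beta0 + beta1 * PSI(SE) + N(0, sigma)`;
#'   `beta1_emats > beta1_other >= 0`.
#' @param distance_range nt range for the planted wAFE-to-sSE 5'
#'   distance (min 450 so the exon layout fits).
#' @param zone_mix probability vector over the five variant zones
#'   (`upstream`, `tss_or_3ss`, `within_exon`, `fivess`, `downstream`).
#' @param variants_per_exon variants drawn per planted EMATS exon.
#' @param pathogenic_frac fraction of variants labelled (likely)
#'   pathogenic.
#' @param hybrid_frac fraction of multi-AFE genes whose second first
#'   exon also receives spliced-in reads (hybrid first/internal profile).
#' @param n_rbp,n_rbp_outliers,rbp_slope,rbp_intercept,rbp_sigma,rbp_shift
#'   RBP knock-down fraction model: fractions on a planted line with
#'   Gaussian scatter, plus `n_rbp_outliers` points displaced by
#'   `rbp_shift`.
#' @param n_noncoding decoy non-protein-coding genes (exercise the
#'   biotype filter).
#' @param noise `TRUE` for Poisson/binomial sampling of junction reads;
#'   `FALSE` for deterministic (rounded expected) counts.
#' @return a validated `emats_sim_config` list.
#' @export
emats_sim_config <- function(seed = 1, n_genes = 200, frac_emats = 0.15,
                             n_tissues = 5, samples_per_tissue = 30,
                             depth_mean = 300,
                             psi_afe_weak = c(2, 6), psi_se_strong = c(8, 2),
                             psi_weak_max = 0.35, psi_strong_min = 0.65,
                             coupling = list(beta0 = 4, beta1_emats = 2,
                                             beta1_other = 0.5, sigma = 0.5),
                             distance_range = c(500, 4500),
                             zone_mix = c(upstream = 0.10, tss_or_3ss = 0.20,
                                          within_exon = 0.45, fivess = 0.15,
                                          downstream = 0.10),
                             variants_per_exon = 2, pathogenic_frac = 0.6,
                             hybrid_frac = 0.3,
                             n_rbp = 250, n_rbp_outliers = 5,
                             rbp_slope = 1.2, rbp_intercept = 0.02,
                             rbp_sigma = 0.005, rbp_shift = 0.08,
                             n_noncoding = 2, noise = TRUE) {
  cfg <- as.list(environment())
  stopifnot(frac_emats >= 0, frac_emats <= 1, n_genes >= 1,
            n_tissues >= 1, samples_per_tissue >= 1, depth_mean >= 0,
            psi_weak_max < psi_strong_min)
  if (abs(sum(zone_mix) - 1) > 1e-9) stop("zone_mix must sum to 1")
  if (!all(names(zone_mix) == c("upstream", "tss_or_3ss", "within_exon",
                                "fivess", "downstream")))
    stop("zone_mix must be named over the five zones in order")
  if (!(coupling$beta1_emats >= coupling$beta1_other && coupling$beta1_other >= 0))
    stop("coupling requires beta1_emats >= beta1_other >= 0")
  if (distance_range[1] < 450) stop("distance_range minimum is 450 nt")
  if (distance_range[2] > 5000) stop("planted EMATS distances must be <= 5000 nt")
  class(cfg) <- "emats_sim_config"
  cfg
}

# Named sub-stream seed derived from the master seed: adding a generator
# never perturbs the draws of another.
sub_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer((h * 1009 + seed) %% 2147483646 + 1)
}

rbeta_trunc <- function(n, shape1, shape2, lower = 0, upper = 1) {
  plo <- stats::pbeta(lower, shape1, shape2)
  phi <- stats::pbeta(upper, shape1, shape2)
  stats::qbeta(stats::runif(n, plo, phi), shape1, shape2)
}

default_tissues <- function(n) {
  pool <- data.frame(
    tissue = c("brain_cortex", "brain_amygdala", "testis", "lung",
               "whole_blood", "liver", "heart", "muscle"),
    group = c("brain", "brain", "testis", "lung", "whole_blood", "liver",
              "heart", "muscle"), stringsAsFactors = FALSE)
  if (n <= nrow(pool)) return(pool[seq_len(n), ])
  extra <- data.frame(tissue = paste0("tissue", seq_len(n - nrow(pool))),
                      group = paste0("tissue", seq_len(n - nrow(pool))),
                      stringsAsFactors = FALSE)
  rbind(pool, extra)
}

# Exon layout of one synthetic gene in transcription coordinates.
# d = planted 5'-5' distance from the first AFE to the focal SE;
# the balancer SE sits > 5 kb from every first-exon 5' coordinate.
gene_layout <- function(gtype, d) {
  b <- max(5600, d + 350)
  ex <- rbind(
    data.frame(name = "A1", s = 0, e = 150),
    if (gtype != "single_afe") data.frame(name = "A2", s = 170, e = 250),
    data.frame(name = "C1", s = 270, e = 370),
    data.frame(name = "SEf", s = d, e = d + 90),
    data.frame(name = "C2", s = d + 150, e = d + 250),
    data.frame(name = "SEb", s = b, e = b + 85),
    data.frame(name = "C3", s = b + 150, e = b + 250),
    data.frame(name = "L", s = b + 350, e = b + 650))
  list(exons = ex, glen = b + 650)
}

gene_transcripts <- function(gtype, hybrid) {
  if (gtype == "single_afe")
    return(list(T1 = c("A1", "C1", "SEf", "C2", "SEb", "C3", "L"),
                T2 = c("A1", "C1", "C2", "C3", "L")))
  tx <- list(T1 = c("A1", "C1", "SEf", "C2", "SEb", "C3", "L"),
             T2 = c("A1", "C1", "C2", "C3", "L"),
             T3 = c("A2", "C1", "SEf", "C2", "C3", "L"))
  if (hybrid) tx$T4 <- c("A1", "A2", "C1", "SEf", "C2", "C3", "L")
  tx
}

#' Generate a synthetic annotation with planted EMATS structure
#'
#' @param config an [emats_sim_config()].
#' @return list with `annotation` (an `emats_annotation`) and `truth`
#'   (the manifest: gene table, genomic exon table, per-tissue true PSI,
#'   sample map, planted pairs).
#' @export
generate_annotation <- function(config) {
  set.seed(sub_seed(config$seed, "annotation"))
  n <- config$n_genes
  n_emats <- round(config$frac_emats * n)
  gtype <- rep("emats", n)
  if (n > n_emats) {
    viol <- c("dist", "strong_afe", "weak_se", "single_afe")
    idx_other <- if (n_emats > 0) setdiff(seq_len(n), sample.int(n, n_emats))
                 else seq_len(n)
    gtype[] <- NA_character_
    gtype[setdiff(seq_len(n), idx_other)] <- "emats"
    gtype[idx_other] <- rep_len(viol, length(idx_other))
  }
  hybrid <- gtype != "single_afe" & stats::runif(n) < config$hybrid_frac
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- switch(gtype[i],
      dist = stats::runif(1, 6000, 9000),
      strong_afe = stats::runif(1, 5020, 5170),
      stats::runif(1, config$distance_range[1], config$distance_range[2]))
  }
  d <- round(d)

  tis <- default_tissues(config$n_tissues)
  samples <- data.frame(
    sample_id = unlist(lapply(tis$tissue, function(t)
      sprintf("%s_s%02d", t, seq_len(config$samples_per_tissue)))),
    tissue = rep(tis$tissue, each = config$samples_per_tissue),
    group = rep(tis$group, each = config$samples_per_tissue),
    stringsAsFactors = FALSE)

  chroms <- c("chrA", "chrB")
  offset <- c(chrA = 2000, chrB = 2000)
  gene_rows <- exon_rows <- tx_rows <- list()
  genes_tab <- list()
  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    chrom <- chroms[(i - 1) %% 2 + 1]
    strand <- if (((i - 1) %/% 2) %% 2 == 0) "+" else "-"
    lay <- gene_layout(gtype[i], d[i])
    g0 <- offset[[chrom]]
    offset[[chrom]] <- g0 + lay$glen + 2000
    ex <- lay$exons
    if (strand == "+") { gs <- g0 + ex$s; ge <- g0 + ex$e
    } else { gs <- g0 + lay$glen - ex$e; ge <- g0 + lay$glen - ex$s }
    exg <- data.frame(gene_id = gid, exon = ex$name, chrom = chrom,
                      strand = strand, start = as.integer(gs),
                      end = as.integer(ge), stringsAsFactors = FALSE)
    txs <- gene_transcripts(gtype[i], hybrid[i])
    for (tn in names(txs)) {
      sel <- exg[match(txs[[tn]], exg$exon), ]
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".", tn),
        chrom = chrom, start = sel$start, end = sel$end, strand = strand,
        stringsAsFactors = FALSE)
    }
    exon_rows[[length(exon_rows) + 1L]] <- exg
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = gid, gene_type = "protein_coding", chrom = chrom,
      start = as.integer(g0), end = as.integer(g0 + lay$glen),
      strand = strand, stringsAsFactors = FALSE)
    genes_tab[[length(genes_tab) + 1L]] <- data.frame(
      gene_id = gid, gtype = gtype[i], is_emats = gtype[i] == "emats",
      hybrid = hybrid[i], distance = d[i], chrom = chrom, strand = strand,
      stringsAsFactors = FALSE)
  }
  # non-coding decoys: two-exon single-transcript genes
  for (k in seq_len(config$n_noncoding)) {
    gid <- sprintf("NC%03d", k)
    chrom <- chroms[(k - 1) %% 2 + 1]
    g0 <- offset[[chrom]]
    offset[[chrom]] <- g0 + 1500 + 2000
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = gid, gene_type = "lncRNA", chrom = chrom,
      start = as.integer(g0), end = as.integer(g0 + 1500), strand = "+",
      stringsAsFactors = FALSE)
    tx_rows[[length(tx_rows) + 1L]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".T1"), chrom = chrom,
      start = as.integer(c(g0, g0 + 1200)), end = as.integer(c(g0 + 200, g0 + 1500)),
      strand = "+", stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  exons <- do.call(rbind, tx_rows)
  annotation <- structure(list(genes = genes, exons = exons),
                          class = "emats_annotation")

  genes_tab <- do.call(rbind, genes_tab)
  exon_tab <- do.call(rbind, exon_rows)

  # per-tissue true PSI: AFE usage u, focal and balancer SE inclusion
  set.seed(sub_seed(config$seed, "psi"))
  wts <- config$psi_afe_weak; sts <- config$psi_se_strong
  wmax <- config$psi_weak_max; smin <- config$psi_strong_min
  nt <- nrow(tis)
  psi <- expand.grid(gene_id = genes_tab$gene_id, tissue = tis$tissue,
                     stringsAsFactors = FALSE)
  m <- nrow(psi)
  gi <- match(psi$gene_id, genes_tab$gene_id)
  u <- rbeta_trunc(m, wts[1], wts[2], upper = wmax)
  u[genes_tab$gtype[gi] == "single_afe"] <- 1
  h <- ifelse(genes_tab$hybrid[gi], 0.5, 0)
  focal_weak <- genes_tab$gtype[gi] == "weak_se"
  pf <- ifelse(focal_weak,
               rbeta_trunc(m, wts[1], wts[2], upper = wmax),
               rbeta_trunc(m, sts[1], sts[2], lower = smin))
  pb <- ifelse(focal_weak,
               rbeta_trunc(m, sts[1], sts[2], lower = smin),
               rbeta_trunc(m, wts[1], wts[2], upper = wmax))
  psi$u <- u
  psi$psi_afe1 <- ifelse(u == 1, 1, u / (1 + u * h))
  psi$psi_afe2 <- ifelse(u == 1, NA_real_, (1 - u + u * h) / (1 + u * h))
  psi$psi_se_focal <- pf
  psi$psi_se_bal <- pb

  pairs <- genes_tab[genes_tab$is_emats, c("gene_id", "distance"), drop = FALSE]
  if (nrow(pairs)) {
    a1 <- exon_tab[exon_tab$exon == "A1", ]
    sef <- exon_tab[exon_tab$exon == "SEf", ]
    pairs$wafe_start <- a1$start[match(pairs$gene_id, a1$gene_id)]
    pairs$wafe_end <- a1$end[match(pairs$gene_id, a1$gene_id)]
    pairs$sse_start <- sef$start[match(pairs$gene_id, sef$gene_id)]
    pairs$sse_end <- sef$end[match(pairs$gene_id, sef$gene_id)]
  }
  rownames(genes_tab) <- rownames(exon_tab) <- rownames(psi) <- NULL
  truth <- list(genes = genes_tab, exons = exon_tab, psi = psi,
                samples = samples, pairs = pairs,
                config = config[c("seed", "n_genes", "frac_emats", "n_tissues",
                                  "samples_per_tissue", "depth_mean", "noise")])
  list(annotation = annotation, truth = truth)
}

#' Generate per-sample junction counts consistent with the planted PSI
#'
#' Each gene-sample pair receives a Poisson total depth; molecules choose
#' a first exon by the planted usage, include the focal and balancer
#' skipped exons binomially at their planted per-tissue PSI, and every
#' junction on the molecule's path contributes one read. With
#' `noise = FALSE` counts are the rounded expected flows.
#'
#' @param annotation,truth output of [generate_annotation()].
#' @param config the [emats_sim_config()].
#' @return junction count data.frame (`sample_id`, `chrom`, `strand`,
#'   `donor`, `acceptor`, `count`), zero-count rows omitted.
#' @export
generate_junction_counts <- function(annotation, truth, config) {
  set.seed(sub_seed(config$seed, "junctions"))
  samples <- truth$samples
  ns <- nrow(samples)
  acc <- list()
  for (g in seq_len(nrow(truth$genes))) {
    ginfo <- truth$genes[g, ]
    exg <- truth$exons[truth$exons$gene_id == ginfo$gene_id, ]
    p <- truth$psi[truth$psi$gene_id == ginfo$gene_id, ]
    p <- p[match(samples$tissue, p$tissue), ]
    h <- if (ginfo$hybrid) 0.5 else 0
    if (config$noise) {
      N <- stats::rpois(ns, config$depth_mean)
      n_a1 <- stats::rbinom(ns, N, p$u)
      n_bridge <- stats::rbinom(ns, n_a1, h)
      n_f <- stats::rbinom(ns, N, p$psi_se_focal)
      n_b <- stats::rbinom(ns, N, p$psi_se_bal)
    } else {
      N <- rep(round(config$depth_mean), ns)
      n_a1 <- round(N * p$u)
      n_bridge <- round(n_a1 * h)
      n_f <- round(N * p$psi_se_focal)
      n_b <- round(N * p$psi_se_bal)
    }
    n_a1d <- n_a1 - n_bridge
    n_a2 <- (N - n_a1) + n_bridge
    jdef <- list(c("A1", "C1"), c("C1", "SEf"), c("C1", "C2"),
                 c("SEf", "C2"), c("C2", "SEb"), c("C2", "C3"),
                 c("SEb", "C3"), c("C3", "L"))
    jcnt <- list(n_a1d, n_f, N - n_f, n_f, n_b, N - n_b, n_b, N)
    if (ginfo$gtype != "single_afe") {
      jdef <- c(jdef, list(c("A1", "A2"), c("A2", "C1")))
      jcnt <- c(jcnt, list(n_bridge, n_a2))
    }
    up <- vapply(jdef, `[`, "", 1L); dn <- vapply(jdef, `[`, "", 2L)
    iu <- match(up, exg$exon); idn <- match(dn, exg$exon)
    donor <- three_prime(exg$start[iu], exg$end[iu], ginfo$strand)
    acceptor <- five_prime(exg$start[idn], exg$end[idn], ginfo$strand)
    nj <- length(jdef)
    acc[[length(acc) + 1L]] <- data.frame(
      sample_id = rep(samples$sample_id, times = nj),
      chrom = ginfo$chrom, strand = ginfo$strand,
      donor = rep(as.integer(donor), each = ns),
      acceptor = rep(as.integer(acceptor), each = ns),
      count = as.integer(unlist(jcnt)), stringsAsFactors = FALSE)
  }
  # decoy non-coding genes: one junction covering their single intron
  nc <- annotation$genes[!annotation$genes$gene_id %in% truth$genes$gene_id, ]
  for (k in seq_len(nrow(nc))) {
    e <- annotation$exons[annotation$exons$gene_id == nc$gene_id[k], ]
    if (nrow(e) < 2L) next
    acc[[length(acc) + 1L]] <- data.frame(
      sample_id = samples$sample_id, chrom = nc$chrom[k], strand = nc$strand[k],
      donor = e$end[1], acceptor = e$start[2],
      count = as.integer(round(config$depth_mean)), stringsAsFactors = FALSE)
  }
  jx <- do.call(rbind, acc)
  jx <- jx[jx$count > 0, , drop = FALSE]
  rownames(jx) <- NULL
  jx
}

#' Generate TPM expression with a planted PSI dependence
#'
#' `log2 TPM = beta0 + beta1 * PSI(focal SE, tissue) + N(0, sigma)` per
#' sample, with the steeper slope `beta1_emats` for EMATS genes.
#'
#' @inheritParams generate_junction_counts
#' @return genes x samples TPM matrix.
#' @export
generate_expression <- function(truth, config) {
  set.seed(sub_seed(config$seed, "expression"))
  cp <- config$coupling
  samples <- truth$samples
  genes <- truth$genes
  m <- matrix(NA_real_, nrow(genes), nrow(samples),
              dimnames = list(genes$gene_id, samples$sample_id))
  for (g in seq_len(nrow(genes))) {
    p <- truth$psi[truth$psi$gene_id == genes$gene_id[g], ]
    pf <- p$psi_se_focal[match(samples$tissue, p$tissue)]
    b1 <- if (genes$is_emats[g]) cp$beta1_emats else cp$beta1_other
    m[g, ] <- 2^(cp$beta0 + b1 * pf + stats::rnorm(nrow(samples), 0, cp$sigma))
  }
  m
}

#' Generate variants across the positional zones of planted EMATS exons
#'
#' For each exon of every planted pair, draws `variants_per_exon`
#' variants whose zone follows `zone_mix`, with a position uniform inside
#' the chosen zone window and a clinical-significance label that is
#' (likely) pathogenic with probability `pathogenic_frac`. A synthetic
#' morbid map covering a subset of EMATS genes (plus decoy non-EMATS
#' genes) is produced alongside.
#'
#' @inheritParams generate_junction_counts
#' @param acc_w,don_w,flank zone window geometry (must match the zone
#'   classifier's).
#' @return list with `variants` (data.frame including the true `zone` and
#'   `exon_id`) and `morbid_map` (data.frame `gene_id`, `phenotype`).
#' @export
generate_variants <- function(truth, config, acc_w = 25, don_w = 6,
                              flank = 1000) {
  set.seed(sub_seed(config$seed, "variants"))
  zones <- names(config$zone_mix)
  ex <- truth$exons[truth$exons$gene_id %in% truth$pairs$gene_id &
                    truth$exons$exon %in% c("A1", "SEf"), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    s <- tx_pos(five_prime(e$start, e$end, e$strand), e$strand)
    en <- tx_pos(three_prime(e$start, e$end, e$strand), e$strand)
    win <- list(upstream = c(s - flank, s - acc_w),
                tss_or_3ss = c(s - acc_w, s),
                within_exon = c(s, en),
                fivess = c(en, en + don_w),
                downstream = c(en + don_w, en + flank))
    for (j in seq_len(config$variants_per_exon)) {
      z <- sample(zones, 1, prob = config$zone_mix)
      q <- win[[z]][1] + sample.int(win[[z]][2] - win[[z]][1], 1) - 1
      pos <- if (e$strand == "+") q else -q - 1
      path <- stats::runif(1) < config$pathogenic_frac
      sig <- if (path) sample(c("Pathogenic", "Likely pathogenic"), 1) else
        sample(c("Benign", "Uncertain significance",
                 "Conflicting interpretations of pathogenicity"), 1)
      nts <- c("A", "C", "G", "T")
      ref <- sample(nts, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = e$chrom, pos = as.integer(pos), ref = ref,
        alt = sample(setdiff(nts, ref), 1), significance = sig,
        phenotype = NA_character_, gene_id = e$gene_id,
        exon_id = paste0(e$gene_id, ":", e$exon),
        exon_role = if (e$exon == "A1") "AFE" else "SE",
        zone = z, stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), significance = character(),
               phenotype = character(), gene_id = character(),
               exon_id = character(), exon_role = character(),
               zone = character(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL

  eg <- unique(truth$pairs$gene_id)
  n_dis <- max(1L, round(0.6 * length(eg)))
  dis <- if (length(eg)) sort(sample(eg, n_dis)) else character(0)
  other <- utils::head(truth$genes$gene_id[!truth$genes$is_emats], 3)
  mm_genes <- c(dis, other)
  morbid <- data.frame(gene_id = mm_genes,
                       phenotype = sprintf("Synthetic syndrome %d",
                                           seq_along(mm_genes)),
                       stringsAsFactors = FALSE)
  if (length(dis) >= 2)  # a couple of genes with two phenotypes
    morbid <- rbind(morbid, data.frame(
      gene_id = dis[1:2],
      phenotype = sprintf("Synthetic syndrome %d",
                          length(mm_genes) + 1:2),
      stringsAsFactors = FALSE))
  list(variants = variants, morbid_map = morbid)
}

#' Generate RBP knock-down fraction tables with planted outliers
#'
#' Differential-gene fractions sit on a planted line in the
#' differential-SE fraction (independently for the up and down
#' directions), with Gaussian scatter; `n_rbp_outliers` RBPs are
#' displaced off the line by `rbp_shift` in both directions.
#'
#' @param config the [emats_sim_config()].
#' @return list with `experiments` (data.frame `rbp`, `frac_up_genes`,
#'   `frac_down_genes`, `frac_up_se`, `frac_down_se`) and `truth`
#'   (data.frame `rbp`, `is_outlier`).
#' @export
generate_rbp_experiments <- function(config) {
  set.seed(sub_seed(config$seed, "rbp"))
  n <- config$n_rbp
  rbp <- sprintf("RBP%03d", seq_len(n))
  out_idx <- sort(sample.int(n, min(config$n_rbp_outliers, n)))
  mk <- function() {
    se <- stats::runif(n, 0.01, 0.2)
    gene <- config$rbp_intercept + config$rbp_slope * se +
      stats::rnorm(n, 0, config$rbp_sigma)
    gene[out_idx] <- gene[out_idx] + config$rbp_shift
    list(se = se, gene = pmin(pmax(gene, 0), 1))
  }
  up <- mk(); down <- mk()
  experiments <- data.frame(rbp = rbp,
                            frac_up_genes = up$gene, frac_down_genes = down$gene,
                            frac_up_se = up$se, frac_down_se = down$se,
                            stringsAsFactors = FALSE)
  list(experiments = experiments,
       truth = data.frame(rbp = rbp, is_outlier = seq_len(n) %in% out_idx,
                          stringsAsFactors = FALSE))
}

#' Run the full synthetic-data generator
#'
#' @param config an [emats_sim_config()] (or arguments forwarded to it).
#' @param out_dir optional directory; when given, writes `annotation.gtf`,
#'   `junctions.tsv`, `tpm.tsv`, `sample_map.tsv`, `variants.tsv`,
#'   `morbid_map.tsv`, `rbp.tsv` and `truth.json`.
#' @param ... forwarded to [emats_sim_config()] when `config` is missing.
#' @return invisible list with all in-memory pieces: `annotation`,
#'   `junctions`, `tpm`, `sample_map`, `variants`, `morbid_map`, `rbp`,
#'   `rbp_truth`, `truth`, and `files` (named paths when `out_dir` was
#'   given).
#' @export
emats_simulate <- function(config = emats_sim_config(...), out_dir = NULL, ...) {
  stopifnot(inherits(config, "emats_sim_config"))
  ga <- generate_annotation(config)
  jx <- generate_junction_counts(ga$annotation, ga$truth, config)
  tpm <- generate_expression(ga$truth, config)
  va <- generate_variants(ga$truth, config)
  rb <- generate_rbp_experiments(config)
  truth <- ga$truth
  truth$variants <- va$variants[, c("chrom", "pos", "gene_id", "exon_id",
                                    "exon_role", "zone")]
  truth$rbp <- rb$truth
  res <- list(annotation = ga$annotation, junctions = jx, tpm = tpm,
              sample_map = truth$samples, variants = va$variants,
              morbid_map = va$morbid_map, rbp = rb$experiments,
              rbp_truth = rb$truth, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(annotation = "annotation.gtf", junctions = "junctions.tsv",
               tpm = "tpm.tsv", sample_map = "sample_map.tsv",
               variants = "variants.tsv", morbid_map = "morbid_map.tsv",
               rbp = "rbp.tsv", truth = "truth.json")
    paths <- stats::setNames(file.path(out_dir, paths), names(paths))
    write_annotation(ga$annotation, paths["annotation"])
    write_tsv(jx, paths["junctions"])
    tpm_tab <- data.frame(gene_id = rownames(tpm),
                          signif(tpm, 6), check.names = FALSE,
                          stringsAsFactors = FALSE)
    write_tsv(tpm_tab, paths["tpm"])
    write_tsv(truth$samples, paths["sample_map"])
    write_tsv(va$variants[, c("chrom", "pos", "ref", "alt", "significance",
                              "phenotype", "gene_id")], paths["variants"])
    write_tsv(va$morbid_map, paths["morbid_map"])
    write_tsv(rb$experiments, paths["rbp"])
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = 12, dataframe = "columns", na = "null")
    res$files <- paths
  }
  invisible(res)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}
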