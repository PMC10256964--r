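#' Spearman coupling between an event's PSI and host-gene TPM
#'
#' Pairs per-sample PSI with per-sample TPM, drops incomplete pairs, then
#' drops observations where the event is constitutively included or
#' excluded (PSI exactly 1 or exactly 0; per-observation rule by default,
#' or the whole event when `constitutive = "per_event"` and PSI is
#' constant at 0 or 1). If at least `min_pairs` observations survive,
#' Spearman's rho (average ranks for ties) is computed; otherwise `NULL`.
#'
#' @param psi_by_sample named numeric PSI vector in `[0, 1]`.
#' @param tpm_by_sample named numeric TPM vector (names matched to
#'   `psi_by_sample`).
#' @param min_pairs minimum surviving paired observations (default 70).
#' @param constitutive `"per_observation"` (default) or `"per_event"`.
#' @param event_id,event_class,gene_id carried through to the record.
#' @return a one-row data.frame (`event_id`, `event_class`, `gene_id`,
#'   `rho`, `n_pairs`) or `NULL` when fewer than `min_pairs` pairs
#'   survive.
#' @export
spearman_coupling <- function(psi_by_sample, tpm_by_sample, min_pairs = 70,
                              constitutive = c("per_observation", "per_event"),
                              event_id = NA_character_,
                              event_class = NA_character_,
                              gene_id = NA_character_) {
  constitutive <- match.arg(constitutive)
  if (!is.numeric(psi_by_sample) || !is.numeric(tpm_by_sample))
    stop("PSI and TPM must be numeric")
  common <- intersect(names(psi_by_sample), names(tpm_by_sample))
  psi <- psi_by_sample[common]; tpm <- tpm_by_sample[common]
  ok <- !is.na(psi) & !is.na(tpm)
  psi <- psi[ok]; tpm <- tpm[ok]
  if (constitutive == "per_observation") {
    keep <- psi > 0 & psi < 1
    psi <- psi[keep]; tpm <- tpm[keep]
  } else if (length(psi) && all(psi %in% c(0, 1)) && length(unique(psi)) == 1L) {
    psi <- numeric(0); tpm <- numeric(0)
  }
  if (length(psi) < min_pairs) return(NULL)
  rho <- stats::cor(psi, tpm, method = "spearman")
  data.frame(event_id = event_id, event_class = event_class,
             gene_id = gene_id, rho = rho, n_pairs = length(psi),
             stringsAsFactors = FALSE)
}

#' Spearman coupling for a PSI matrix against a TPM matrix
#'
#' @param psi events x samples PSI matrix (rownames = event IDs).
#' @param tpm genes x samples TPM matrix (rownames = gene IDs).
#' @param event_genes character vector: host gene of each PSI row.
#' @param event_class class label(s) for the events (recycled).
#' @inheritParams spearman_coupling
#' @return data.frame of coupling records (events failing the
#'   `min_pairs` rule are omitted).
#' @export
coupling_records <- function(psi, tpm, event_genes, event_class = "SE",
                             min_pairs = 70,
                             constitutive = c("per_observation", "per_event")) {
  constitutive <- match.arg(constitutive)
  event_class <- rep_len(event_class, nrow(psi))
  recs <- lapply(seq_len(nrow(psi)), function(i) {
    g <- event_genes[i]
    if (!g %in% rownames(tpm)) return(NULL)
    spearman_coupling(psi[i, ], tpm[g, ], min_pairs, constitutive,
                      event_id = rownames(psi)[i],
                      event_class = event_class[i], gene_id = g)
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs))
    return(data.frame(event_id = character(), event_class = character(),
                      gene_id = character(), rho = numeric(),
                      n_pairs = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Merge event-level rho values at the gene level
#'
#' @param records coupling record data.frame (see [coupling_records()]).
#' @param by `"gene"` or `"gene_class"` (gene within event class).
#' @param merge `"mean"` (default) or `"median"`.
#' @return data.frame `gene_id` (and `event_class` when requested),
#'   `rho`, `n_events`.
#' @export
merge_rho_gene_level <- function(records, by = c("gene", "gene_class"),
                                 merge = c("mean", "median")) {
  by <- match.arg(by); merge <- match.arg(merge)
  fun <- if (merge == "mean") mean else stats::median
  if (nrow(records) == 0L)
    return(data.frame(gene_id = character(), rho = numeric(),
                      n_events = integer(), stringsAsFactors = FALSE))
  key <- if (by == "gene") records$gene_id else
    paste(records$gene_id, records$event_class, sep = "\r")
  rho <- tapply(records$rho, key, fun)
  n <- tapply(records$rho, key, length)
  out <- data.frame(gene_id = sub("\r.*", "", names(rho)),
                    rho = as.numeric(rho), n_events = as.integer(n),
                    stringsAsFactors = FALSE)
  if (by == "gene_class") out$event_class <- sub(".*\r", "", names(rho))
  rownames(out) <- NULL
  out
}

#' Equal-probability quantile bins
#'
#' Assigns each value to one of `k` bins by empirical quantiles, breaking
#' ties by rank order so bin sizes are as equal as possible (quartiles
#' for `k = 4`, sextiles for `k = 6`).
#'
#' @param values numeric vector (NAs get NA bins).
#' @param k number of bins.
#' @param ties policy when all values are identical: `"error"` (default)
#'   or `"single"` (one bin).
#' @return integer bin labels in `1..k`.
#' @export
bin_by_quantiles <- function(values, k, ties = c("error", "single")) {
  ties <- match.arg(ties)
  ok <- !is.na(values)
  out <- rep(NA_integer_, length(values))
  v <- values[ok]
  if (!length(v)) return(out)
  if (length(unique(v)) == 1L) {
    if (ties == "error") stop("all values identical; cannot form ", k, " quantile bins")
    out[ok] <- 1L
    return(out)
  }
  r <- rank(v, ties.method = "first")
  out[ok] <- as.integer(ceiling(r * k / length(v)))
  out
}

#' Compare coupling between EMATS and non-EMATS genes
#'
#' Two-sided independent (Welch) t-test on the two per-gene rho samples,
#' with the significance-star scheme *p < 0.05, **p < 0.01, ***p < 0.001,
#' ****p < 0.0001, *****p < 0.00001.
#'
#' @param rho_emats,rho_other numeric rho vectors (each needs n >= 2).
#' @return list with `mean_emats`, `mean_other`, `t`, `p`, `stars`,
#'   `test` (the htest object).
#' @export
compare_emats_vs_other <- function(rho_emats, rho_other) {
  rho_emats <- rho_emats[!is.na(rho_emats)]
  rho_other <- rho_other[!is.na(rho_other)]
  if (length(rho_emats) < 2L || length(rho_other) < 2L)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(rho_emats, rho_other, alternative = "two.sided",
                      var.equal = FALSE)
  list(mean_emats = mean(rho_emats), mean_other = mean(rho_other),
       t = unname(tt$statistic), p = tt$p.value,
       stars = p_stars(tt$p.value), test = tt)
}

p_stars <- function(p) {
  cuts <- c(0.05, 0.01, 0.001, 1e-4, 1e-5)
  paste(rep("*", sum(p < cuts)), collapse = "")
}

#' Differential up/down fractions for one RBP knock-down
#'
#' A differential gene expression or exon-skipping event is significant
#' when its multiple-testing corrected p-value is strictly below 0.05; it
#' counts as upregulated when the knock-down minus control difference is
#' strictly greater than 0 and downregulated when strictly less.
#' Fractions are taken against the total number of genes or exons the
#' respective differential tool reported.
#'
#' @param diff_gene_table data.frame with columns `adj_p`, `delta`.
#' @param diff_se_table data.frame with columns `adj_p`, `delta`.
#' @param total_genes,total_se totals reported by the tools (> 0);
#'   default: the table row counts.
#' @param rbp RBP name carried into the record.
#' @param alpha significance level (strict, default 0.05).
#' @return one-row data.frame: `rbp`, `frac_up_genes`, `frac_down_genes`,
#'   `frac_up_se`, `frac_down_se`.
#' @export
rbp_fractions <- function(diff_gene_table, diff_se_table,
                          total_genes = nrow(diff_gene_table),
                          total_se = nrow(diff_se_table),
                          rbp = NA_character_, alpha = 0.05) {
  if (total_genes <= 0 || total_se <= 0) stop("totals must be positive")
  frac <- function(tab, total, dirn) {
    sig <- tab$adj_p < alpha
    d <- if (dirn > 0) tab$delta > 0 else tab$delta < 0
    sum(sig & d, na.rm = TRUE) / total
  }
  data.frame(rbp = rbp,
             frac_up_genes = frac(diff_gene_table, total_genes, 1),
             frac_down_genes = frac(diff_gene_table, total_genes, -1),
             frac_up_se = frac(diff_se_table, total_se, 1),
             frac_down_se = frac(diff_se_table, total_se, -1),
             stringsAsFactors = FALSE)
}

#' Select the RBPs with the largest regression residuals
#'
#' Ordinary least squares of the differential-gene fraction on the
#' differential-skipped-exon fraction, fitted separately for the
#' upregulated and downregulated directions; the residual magnitude is
#' `|observed - fitted|`. The union of the top-`k` RBPs per regression is
#' returned, deduplicated, with ties broken by RBP name so the selection
#' is deterministic.
#'
#' @param experiments data.frame with columns `rbp`, `frac_up_genes`,
#'   `frac_down_genes`, `frac_up_se`, `frac_down_se` (one row per
#'   knock-down).
#' @param k top residuals per regression (default 17); clamped to the
#'   number of experiments.
#' @return list with `selected` (character vector of unique RBP names),
#'   `per_direction` (list of the top-k per direction), `fits` (the two
#'   lm objects) and `residuals` (data.frame per RBP and direction).
#' @export
residual_selection <- function(experiments, k = 17) {
  n <- nrow(experiments)
  if (n == 0L) stop("no experiments supplied")
  k <- min(k, n)
  pick <- function(gene_col, se_col) {
    fit <- stats::lm(experiments[[gene_col]] ~ experiments[[se_col]])
    res <- abs(stats::resid(fit))
    res[res < 1e-12] <- 0  # numerically-zero residuals tie; break by name
    ord <- order(-res, experiments$rbp)
    list(fit = fit, res = res, top = experiments$rbp[ord[seq_len(k)]])
  }
  up <- pick("frac_up_genes", "frac_up_se")
  down <- pick("frac_down_genes", "frac_down_se")
  list(selected = sort(unique(c(up$top, down$top))),
       per_direction = list(up = up$top, down = down$top),
       fits = list(up = up$fit, down = down$fit),
       residuals = data.frame(rbp = experiments$rbp,
                              residual_up = unname(up$res),
                              residual_down = unname(down$res),
                              stringsAsFactors = FALSE))
}
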