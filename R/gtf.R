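#' Parse a GTF/GFF3 gene annotation
#'
#' Reads gene/transcript/exon features into the package's annotation
#' container. GTF 1-based closed coordinates are converted to 0-based
#' half-open on entry; all downstream interval arithmetic uses the
#' half-open convention.
#'
#' @param path path to a GTF or GFF3 file (plain or gzip).
#' @param gene_type_filter keep only genes of this biotype (e.g.
#'   `"protein_coding"`); `NULL` keeps everything. Matches the `gene_type`
#'   (GENCODE) or `gene_biotype` (Ensembl) attribute.
#' @param format `"auto"` (by extension), `"gtf"` or `"gff3"`.
#' @return an object of class `emats_annotation`: a list with
#'   \describe{
#'     \item{genes}{data.frame `gene_id`, `gene_type`, `chrom`, `start`,
#'       `end`, `strand` (gene span from the gene feature when present,
#'       otherwise the min/max over the gene's exons).}
#'     \item{exons}{data.frame `gene_id`, `transcript_id`, `chrom`,
#'       `start`, `end`, `strand`, one row per annotated exon.}
#'   }
#' @export
parse_annotation <- function(path, gene_type_filter = "protein_coding",
                             format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "gtf"
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (any(!df$strand %in% c("+", "-")))
    stop("unknown strand symbol in annotation: ",
         paste(unique(df$strand[!df$strand %in% c("+", "-")]), collapse = ", "))
  # 1-based closed -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  df$type <- as.character(df$type)
  if (is.null(df$gene_id)) stop("annotation has no gene_id attribute")
  biotype <- if (!is.null(df$gene_type)) df$gene_type
             else if (!is.null(df$gene_biotype)) df$gene_biotype
             else rep(NA_character_, nrow(df))

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("annotation contains no exon features")
  if (is.null(ex$transcript_id) || any(is.na(ex$transcript_id) | ex$transcript_id == ""))
    stop("exon feature without a parent transcript_id")
  exons <- data.frame(gene_id = ex$gene_id, transcript_id = ex$transcript_id,
                      chrom = ex$chrom, start = ex$start0, end = ex$end0,
                      strand = ex$strand, stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
  rownames(exons) <- NULL

  gn <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gn) > 0L) {
    genes <- data.frame(gene_id = gn$gene_id,
                        gene_type = biotype[df$type == "gene"],
                        chrom = gn$chrom, start = gn$start0, end = gn$end0,
                        strand = gn$strand, stringsAsFactors = FALSE)
  } else {
    genes <- derive_gene_spans(exons)
    bt <- tapply(biotype[df$type == "exon"], ex$gene_id, function(x) x[1])
    genes$gene_type <- as.character(bt[genes$gene_id])
  }
  # genes present only through exons (no gene row) still get a span
  missing_span <- setdiff(unique(exons$gene_id), genes$gene_id)
  if (length(missing_span)) {
    extra <- derive_gene_spans(exons[exons$gene_id %in% missing_span, ])
    extra$gene_type <- NA_character_
    genes <- rbind(genes[, names(extra)], extra)
  }
  genes <- genes[!duplicated(genes$gene_id), ]
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL

  if (!is.null(gene_type_filter)) {
    keep <- genes$gene_id[!is.na(genes$gene_type) &
                          genes$gene_type == gene_type_filter]
    genes <- genes[genes$gene_id %in% keep, , drop = FALSE]
    exons <- exons[exons$gene_id %in% keep, , drop = FALSE]
    rownames(genes) <- rownames(exons) <- NULL
  }
  structure(list(genes = genes, exons = exons), class = "emats_annotation")
}

derive_gene_spans <- function(exons) {
  sp <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1], gene_type = NA_character_,
               chrom = e$chrom[1], start = min(e$start), end = max(e$end),
               strand = e$strand[1], stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp
}

# Structural pre-validation so malformed input fails with a line number,
# which rtracklayer's parser does not report.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(body)) stop("annotation file has no feature lines: ", path)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  lineno <- which(body)
  if (any(nf < 9L))
    stop("malformed annotation line ", lineno[which(nf < 9L)[1]],
         ": expected 9 tab-separated fields, found ", nf[which(nf < 9L)[1]])
  strands <- vapply(fields, `[`, "", 7L)
  bad <- !strands %in% c("+", "-")
  if (any(bad))
    stop("unknown strand symbol '", strands[which(bad)[1]],
         "' at annotation line ", lineno[which(bad)[1]])
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  badc <- is.na(starts) | is.na(ends)
  if (any(badc))
    stop("malformed annotation line ", lineno[which(badc)[1]],
         ": non-numeric coordinates")
  invisible(TRUE)
}

#' Write an annotation back to GTF
#'
#' Emits gene and exon features with `gene_id`, `gene_type` and
#' `transcript_id` attributes; internal 0-based half-open coordinates are
#' converted back to GTF's 1-based closed convention, so
#' parse -> write -> parse preserves every interval exactly.
#'
#' @param ann an `emats_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "emats_annotation"))
  g <- ann$genes
  gl <- sprintf("%s\temats\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_type \"%s\";",
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
                ifelse(is.na(g$gene_type), "NA", g$gene_type))
  e <- ann$exons
  gt <- g$gene_type[match(e$gene_id, g$gene_id)]
  el <- sprintf(paste0("%s\temats\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                       "transcript_id \"%s\"; gene_type \"%s\";"),
                e$chrom, e$start + 1L, e$end, e$strand, e$gene_id,
                e$transcript_id, ifelse(is.na(gt), "NA", gt))
  ord <- order(c(g$chrom, e$chrom), c(g$start, e$start))
  writeLines(c(gl, el)[ord], path)
  invisible(path)
}

#' Count unique genes of one biotype in an annotation file
#'
#' Convenience counter used to size an annotation before analysis, e.g. the
#' number of distinct protein-coding gene IDs in a GENCODE release.
#'
#' @inheritParams parse_annotation
#' @return integer count of unique gene IDs passing the filter.
#' @export
count_genes <- function(path, gene_type_filter = "protein_coding",
                        format = c("auto", "gtf", "gff3")) {
  ann <- parse_annotation(path, gene_type_filter, format)
  length(unique(ann$genes$gene_id))
}

#' Read per-sample splice-junction counts
#'
#' Expects a tab-separated table with header
#' `sample_id  chrom  strand  donor  acceptor  count`. `donor` and
#' `acceptor` are transcription-direction boundary coordinates in the
#' 0-based half-open convention: the donor equals the 3' boundary of the
#' upstream exon and the acceptor the 5' boundary of the downstream exon
#' (on `-` the donor is the genomic start of the genomically-right exon).
#'
#' @param path TSV path.
#' @return data.frame of junction counts.
#' @export
read_junctions <- function(path) {
  jx <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "strand", "donor", "acceptor", "count")
  miss <- setdiff(need, names(jx))
  if (length(miss)) stop("junction table lacks columns: ", paste(miss, collapse = ", "))
  if (any(jx$count < 0)) stop("negative junction counts")
  if (any(!jx$strand %in% c("+", "-"))) stop("unknown strand symbol in junction table")
  jx$donor <- as.integer(jx$donor)
  jx$acceptor <- as.integer(jx$acceptor)
  jx
}

#' Read a sample-to-tissue map
#'
#' @param path TSV with columns `sample_id`, `tissue` and optionally
#'   `group` (tissue group, e.g. all brain sub-types share group "brain");
#'   `group` defaults to `tissue`.
#' @return data.frame `sample_id`, `tissue`, `group`.
#' @export
read_sample_map <- function(path) {
  sm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(sm)))
    stop("sample map needs columns sample_id, tissue")
  if (is.null(sm$group)) sm$group <- sm$tissue
  sm
}

#' Read a gene-by-sample TPM expression matrix
#'
#' @param path TSV whose first column is `gene_id`, remaining columns one
#'   per sample.
#' @return numeric matrix, rows = genes, columns = samples.
#' @export
read_tpm <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "gene_id") stop("TPM table must start with a gene_id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write meta-exons or EMATS pair regions as BED6
#'
#' Coordinates are already 0-based half-open so they map directly onto
#' BED. The score column is `round(median PSI * 1000)` where a median PSI
#' is available, else 0. For pair tables both exons of a pair are written
#' as two lines sharing the pair ID in the name field.
#'
#' @param features a meta-exon data.frame (columns `chrom`, `start`, `end`,
#'   `strand`, `exon_id`, optionally `median_psi`) or an EMATS pair
#'   data.frame as produced by [find_emats_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(features, path) {
  header <- "# BED6: chrom start end name score strand"
  if (is.null(features) || nrow(features) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (all(c("wafe_start", "sse_start") %in% names(features))) {
    f <- features
    lines <- c(
      sprintf("%s\t%d\t%d\t%s|wAFE\t%d\t%s", f$chrom, f$wafe_start, f$wafe_end,
              f$pair_id, bed_score(f$wafe_median_psi), f$strand),
      sprintf("%s\t%d\t%d\t%s|sSE\t%d\t%s", f$chrom, f$sse_start, f$sse_end,
              f$pair_id, bed_score(f$sse_median_psi), f$strand))
  } else {
    sc <- if (is.null(features$median_psi)) rep(NA_real_, nrow(features))
          else features$median_psi
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", features$chrom, features$start,
                     features$end, features$exon_id, bed_score(sc),
                     features$strand)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

bed_score <- function(psi) {
  s <- ifelse(is.na(psi), 0, round(psi * 1000))
  as.integer(pmin(pmax(s, 0), 1000))
}

#' Read a BED6 file written by [write_regions()]
#'
#' @param path BED path.
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = f[, 1], start = as.integer(f[, 2]), end = as.integer(f[, 3]),
             name = f[, 4], score = as.integer(f[, 5]), strand = f[, 6],
             stringsAsFactors = FALSE)
}

#' Read a variant table (TSV or VCF)
#'
#' TSV input needs columns `chrom`, `pos` (0-based), `ref`, `alt`,
#' `significance`, and optionally `phenotype` and `gene_id`. VCF input
#' (1-based, converted to 0-based) takes the clinical significance from
#' the `CLNSIG` INFO key and the gene from `GENEINFO`.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `significance`,
#'   `phenotype`, `gene_id`.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    v <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "significance")
    miss <- setdiff(need, names(v))
    if (length(miss)) stop("variant table lacks columns: ", paste(miss, collapse = ", "))
    if (is.null(v$phenotype)) v$phenotype <- NA_character_
    if (is.null(v$gene_id)) v$gene_id <- NA_character_
    if (any(v$pos < 0)) stop("variant positions must be >= 0 (0-based)")
    return(v[, c("chrom", "pos", "ref", "alt", "significance", "phenotype", "gene_id")])
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info1 <- function(key) {
    m <- regmatches(fx$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"), fx$INFO))
    out <- rep(NA_character_, nrow(fx))
    hit <- grepl(paste0(key, "="), fx$INFO)
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  sig <- info1("CLNSIG")
  gene <- sub(":.*", "", info1("GENEINFO"))
  data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS) - 1L,
             ref = fx$REF, alt = fx$ALT,
             significance = gsub("_", " ", sig),
             phenotype = NA_character_, gene_id = gene,
             stringsAsFactors = FALSE)
}
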