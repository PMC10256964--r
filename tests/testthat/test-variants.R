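test_that("pathogenic filtering keeps (likely) pathogenic, drops conflicting", {
  v <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "C",
                  significance = c("Pathogenic", "Likely pathogenic", "Benign",
                                   "Uncertain significance",
                                   "Conflicting interpretations of pathogenicity"),
                  stringsAsFactors = FALSE)
  f <- filter_pathogenic(v)
  expect_equal(f$significance, c("Pathogenic", "Likely pathogenic"))
  # idempotent
  expect_equal(filter_pathogenic(f), f)
  expect_equal(nrow(filter_pathogenic(v[0, ])), 0L)
  # case-insensitive
  v$significance <- tolower(v$significance)
  expect_equal(nrow(filter_pathogenic(v)), 2L)
})

test_that("zone classification follows the strand-aware window geometry", {
  exon <- data.frame(chrom = "chr1", start = 3000L, end = 3100L, strand = "+")
  expect_equal(classify_zone(3050, exon), "within_exon")
  expect_equal(classify_zone(3102, exon, don_w = 6), "fivess")
  expect_equal(classify_zone(2950, exon, acc_w = 25, flank = 1000), "upstream")
  expect_equal(classify_zone(2990, exon, acc_w = 25), "tss_or_3ss")
  expect_equal(classify_zone(3500, exon), "downstream")
  expect_true(is.na(classify_zone(5000, exon, flank = 1000)))
  expect_error(classify_zone(3050, exon, chrom = "chr2"), "chromosome")
  expect_error(classify_zone(3050, exon, acc_w = 1000, flank = 1000), "flank")
})

test_that("zones tile the flank exactly once (property, both strands)", {
  set.seed(12)
  for (rep in 1:30) {
    start <- sample.int(5e4, 1) + 2000L
    exon <- data.frame(chrom = "c", start = start,
                       end = start + sample(30:400, 1),
                       strand = sample(c("+", "-"), 1))
    acc_w <- sample(5:40, 1); don_w <- sample(2:10, 1)
    flank <- sample(100:500, 1)
    pos <- (exon$start - flank):(exon$end + flank - 1L)
    z <- classify_zone(pos, exon, acc_w = acc_w, don_w = don_w, flank = flank)
    expect_false(any(is.na(z)))
    tab <- table(z)
    expect_equal(unname(tab["within_exon"]), exon$end - exon$start)
    expect_equal(unname(tab["tss_or_3ss"]), acc_w)
    expect_equal(unname(tab["fivess"]), don_w)
    expect_equal(unname(tab["upstream"]), flank - acc_w)
    expect_equal(unname(tab["downstream"]), flank - don_w)
    expect_equal(sum(tab), 2L * flank + (exon$end - exon$start))
    # strand mirror: reflecting coordinates and flipping strand swaps
    # upstream<->downstream and tss_or_3ss<->fivess
    C <- 2L * exon$start + 1000L
    exon_m <- data.frame(chrom = "c", start = C - exon$end, end = C - exon$start,
                         strand = if (exon$strand == "+") "-" else "+")
    zm <- classify_zone(C - pos - 1L, exon_m, acc_w = acc_w, don_w = don_w,
                        flank = flank)
    expect_equal(zm, z)
  }
})

test_that("disease-table merging inner-joins genes then intersects regions", {
  catalog <- structure(list(pairs = data.frame(
    pair_id = "g1:P1", gene_id = "g1", chrom = "chr1", strand = "+",
    wafe_id = "g1:ME1", wafe_start = 1000L, wafe_end = 1200L,
    wafe_median_psi = 0.2, sse_id = "g1:ME3", sse_start = 3000L,
    sse_end = 3100L, sse_median_psi = 0.9, distance_5p = 2000L,
    stringsAsFactors = FALSE), genes = "g1"), class = "emats_catalog")
  variants <- data.frame(chrom = "chr1", pos = c(1100L, 3050L, 50000L),
                         ref = "A", alt = "G", significance = "Pathogenic",
                         phenotype = NA_character_,
                         gene_id = c("g1", "g2", "g1"), stringsAsFactors = FALSE)
  morbid <- data.frame(gene_id = c("g1", "g1", "g3"),
                       phenotype = c("Syndrome 1", "Syndrome 2", "Syndrome 3"),
                       stringsAsFactors = FALSE)
  merged <- merge_disease_tables(morbid, variants, catalog)
  # hand-joined oracle: the two in-region variants (both in g1 regions,
  # the distal one is outside every flank) x two g1 phenotypes = 4 rows
  expect_equal(nrow(merged), 4L)
  expect_setequal(unique(merged$phenotype), c("Syndrome 1", "Syndrome 2"))
  expect_false(50000L %in% merged$pos)

  # a gene absent from the morbid map drops out (inner join)
  morbid_g3 <- morbid[morbid$gene_id == "g3", , drop = FALSE]
  expect_equal(nrow(merge_disease_tables(morbid_g3, variants, catalog)), 0L)
  expect_error(merge_disease_tables(data.frame(symbol = "g1"), variants, catalog),
               "join")
})

test_that("zone counting reports per-zone totals and distinct regions", {
  calls <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                      zone = "within_exon", exon_id = "g1:ME1",
                      stringsAsFactors = FALSE)
  zc <- count_zone_regions(calls)
  expect_equal(unname(zc$per_zone["within_exon"]), 3L)
  expect_equal(sum(zc$per_zone), 3L)
  expect_equal(zc$n_window_regions, 1L)
  expect_equal(zc$n_exon_regions, 1L)
  z0 <- count_zone_regions(calls[0, ])
  expect_true(all(z0$per_zone == 0L))
})

test_that("generated variants round-trip through the zone classifier", {
  sim <- small_sim()
  sc <- emats_scan(sim$annotation, sim$junctions, sim$sample_map,
                   per_tissue = FALSE)
  calls <- annotate_variant_zones(sim$variants, sc$catalog)
  truth <- sim$variants
  key <- paste(calls$chrom, calls$pos, calls$exon_role)
  tkey <- paste(truth$chrom, truth$pos, truth$exon_role)
  m <- match(tkey, key)
  expect_false(any(is.na(m)))                  # every planted variant annotated
  expect_equal(calls$zone[m], truth$zone)      # with its planted zone
  # zone composition matches the planted mix in counts
  zc <- count_zone_regions(calls[m, ])
  expect_equal(unname(zc$per_zone), as.integer(table(
    factor(truth$zone, levels = names(zc$per_zone)))))
})

test_that("variant tables read from TSV and VCF agree", {
  skip_if_not_installed("vcfR")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tsignificance\tphenotype\tgene_id",
               "chr1\t999\tA\tG\tPathogenic\tNA\tg1"), tsv)
  v1 <- read_variants(tsv)
  expect_equal(v1$pos, 999L)

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"sig\">",
               "##INFO=<ID=GENEINFO,Number=.,Type=String,Description=\"gene\">",
               "##contig=<ID=chr1>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t1000\t.\tA\tG\t.\t.\tCLNSIG=Pathogenic;GENEINFO=g1:123"),
             vcf)
  v2 <- read_variants(vcf)
  expect_equal(v2$pos, 999L)       # 1-based VCF -> 0-based internal
  expect_equal(v2$significance, "Pathogenic")
  expect_equal(v2$gene_id, "g1")
})
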