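test_that("GTF parsing converts coordinates and filters by biotype", {
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"))
  ann <- parse_annotation(gtf, gene_type_filter = "protein_coding")
  expect_equal(ann$genes$gene_id, "PC1")
  # 1-based closed [1001, 1200] -> 0-based half-open [1000, 1200)
  expect_equal(ann$exons$start[1], 1000L)
  expect_equal(ann$exons$end[1], 1200L)
  expect_equal(nrow(ann$exons), 5L)

  all_ann <- parse_annotation(gtf, gene_type_filter = NULL)
  expect_setequal(all_ann$genes$gene_id, c("PC1", "NC1"))
  expect_equal(count_genes(gtf, "protein_coding"), 1L)
})

test_that("malformed annotation input fails with a line-numbered error", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\texon\t100\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1\ttoy\texon\t100"), bad)
  expect_error(parse_annotation(bad), "line 2")

  badstrand <- tempfile(fileext = ".gtf")
  writeLines('chr1\ttoy\texon\t100\t200\t.\t?\t.\tgene_id "g"; transcript_id "t";',
             badstrand)
  expect_error(parse_annotation(badstrand), "strand")

  orphan <- tempfile(fileext = ".gtf")
  writeLines('chr1\ttoy\texon\t100\t200\t.\t+\t.\tgene_id "g";', orphan)
  expect_error(parse_annotation(orphan, gene_type_filter = NULL), "transcript")
})

test_that("meta-exon collapsing merges overlapping exons and nothing else", {
  ex <- make_exons("g1", "chr1", "+",
                   list(t1 = rbind(c(100L, 200L)), t2 = rbind(c(150L, 250L))))
  m <- collapse_meta_exons(ex)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 250L))
  expect_equal(m$transcripts, "t1,t2")

  # disjoint exons stay separate; bookended exons ([100,200) + [200,300))
  # share only a boundary and are NOT merged
  ex2 <- make_exons("g1", "chr1", "+",
                    list(t1 = rbind(c(100L, 200L), c(300L, 400L)),
                         t2 = rbind(c(200L, 300L))))
  m2 <- collapse_meta_exons(ex2)
  expect_equal(m2$start, c(100L, 200L, 300L))

  # single transcript, single exon: identity
  ex3 <- make_exons("g1", "chr1", "-", list(t1 = rbind(c(5L, 60L))))
  m3 <- collapse_meta_exons(ex3)
  expect_equal(c(m3$start, m3$end), c(5L, 60L))
})

test_that("meta-exon collapsing equals the per-base union oracle (property)", {
  set.seed(101)
  for (rep in 1:60) {
    iv <- random_interval_set()
    start <- iv$start; end <- iv$end
    n <- length(start)
    strand <- sample(c("+", "-"), 1)
    ntx <- sample(1:4, 1)
    ex <- data.frame(gene_id = "g", transcript_id = sample(paste0("t", 1:ntx), n,
                                                           replace = TRUE),
                     chrom = "chr1", start = start, end = end, strand = strand,
                     stringsAsFactors = FALSE)
    m <- collapse_meta_exons(ex)
    m <- m[order(m$start), ]
    o <- oracle_union(start, end)
    expect_equal(m$start, o$start)
    expect_equal(m$end, o$end)
    # idempotence: collapsing the collapsed set is the identity
    m2 <- collapse_meta_exons(data.frame(gene_id = "g", transcript_id = "t1",
                                         chrom = "chr1", start = m$start,
                                         end = m$end, strand = strand))
    m2 <- m2[order(m2$start), ]
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
  }
})

test_that("alternative flags follow transcript membership", {
  ex <- make_exons("g1", "chr1", "+",
                   list(t1 = rbind(c(100L, 200L), c(400L, 500L)),
                        t2 = rbind(c(100L, 200L), c(400L, 500L)),
                        t3 = rbind(c(100L, 200L))))
  m <- collapse_meta_exons(ex)
  expect_false(m$is_alternative[m$start == 100])  # in all transcripts
  expect_true(m$is_alternative[m$start == 400])   # in 2 of 3
  expect_true(flag_alternative(m[m$start == 400, ], ex))
  expect_false(flag_alternative(m[m$start == 100, ], ex))

  # single-transcript gene: every exon constitutive (vacuous all-transcripts rule)
  ex1 <- make_exons("g1", "chr1", "+", list(t1 = rbind(c(100L, 200L))))
  expect_false(collapse_meta_exons(ex1)$is_alternative)
})

test_that("gene architecture metrics follow the half-open formulas", {
  expect_equal(gene_length_kb(0, 1000), 1.0)
  expect_equal(gene_length_kb(10000, 12500), 2.5)
  expect_equal(gene_length_kb(5, 6), 0.001)
  expect_error(gene_length_kb(10, 10))

  expect_equal(exon_distance_to_gene_5prime(2000, 2100, 1000, 9000, "+"), 1000L)
  expect_equal(exon_distance_to_gene_5prime(7900, 8000, 1000, 9000, "-"), 1000L)
  expect_equal(exon_distance_to_gene_5prime(1000, 1100, 1000, 9000, "+"), 0L)
  expect_equal(exon_distance_to_gene_5prime(8900, 9000, 1000, 9000, "-"), 0L)
  expect_error(exon_distance_to_gene_5prime(900, 1100, 1000, 9000, "+"), "outside")

  # strand mirror: reflecting through a constant and flipping strand
  # leaves both metrics unchanged
  C <- 20000
  set.seed(7)
  for (i in 1:20) {
    gs <- sample.int(5000, 1); ge <- gs + sample(2000:8000, 1)
    es <- gs + sample.int(1000, 1); ee <- es + 100
    expect_equal(gene_length_kb(C - ge, C - gs), gene_length_kb(gs, ge))
    expect_equal(
      exon_distance_to_gene_5prime(C - ee, C - es, C - ge, C - gs, "-"),
      exon_distance_to_gene_5prime(es, ee, gs, ge, "+"))
  }
})

test_that("interval validation rejects degenerate input", {
  expect_error(genome_interval("chr1", -1, 10, "+"), ">= 0")
  expect_error(genome_interval("chr1", 10, 10, "+"), "half-open")
  expect_error(genome_interval("chr1", 0, 10, "?"), "strand")
  gi <- genome_interval("chr1", 1000, 1200, "+")
  expect_equal(five_prime(gi$start, gi$end, gi$strand), 1000)
  expect_equal(three_prime(gi$start, gi$end, "-"), 1000)
})

test_that("BED output round-trips and encodes PSI scores", {
  meta <- data.frame(chrom = "chr1", start = 1000L, end = 1200L, strand = "+",
                     exon_id = "g:ME1", median_psi = 0.5)
  path <- tempfile(fileext = ".bed")
  write_regions(meta, path)
  b <- read_bed(path)
  expect_equal(b$start, 1000L)
  expect_equal(b$end, 1200L)
  expect_equal(b$score, 500L)
  expect_equal(b$strand, "+")

  write_regions(meta[0, ], path)
  expect_equal(nrow(read_bed(path)), 0L)
  expect_true(startsWith(readLines(path)[1], "#"))

  pairs <- data.frame(pair_id = "g:P1", gene_id = "g", chrom = "chr1",
                      strand = "+", wafe_id = "g:ME1", wafe_start = 1000L,
                      wafe_end = 1200L, wafe_median_psi = 0.2,
                      sse_id = "g:ME3", sse_start = 3000L, sse_end = 3100L,
                      sse_median_psi = 0.9, distance_5p = 2000L)
  write_regions(pairs, path)
  b2 <- read_bed(path)
  expect_equal(nrow(b2), 2L)
  expect_true(all(grepl("g:P1", b2$name)))
})

test_that("annotation writing round-trips through the parser", {
  sim <- small_sim()
  p1 <- tempfile(fileext = ".gtf")
  write_annotation(sim$annotation, p1)
  back <- parse_annotation(p1, gene_type_filter = NULL)
  a <- sim$annotation$exons[order(sim$annotation$exons$gene_id,
                                  sim$annotation$exons$transcript_id,
                                  sim$annotation$exons$start), ]
  b <- back$exons[order(back$exons$gene_id, back$exons$transcript_id,
                        back$exons$start), ]
  expect_equal(b$start, a$start)
  expect_equal(b$end, a$end)
  expect_equal(b$strand, a$strand)
  g <- back$genes[match(sim$annotation$genes$gene_id, back$genes$gene_id), ]
  expect_equal(g$start, sim$annotation$genes$start)
  expect_equal(g$end, sim$annotation$genes$end)
})
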