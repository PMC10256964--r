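mk_exon <- function(gene, id, start, end, strand, call = NA, psi = NA) {
  data.frame(exon_id = id, gene_id = gene, chrom = "chr1", start = start,
             end = end, strand = strand, median_psi = psi, call = call,
             stringsAsFactors = FALSE)
}

test_that("EMATS pairing enforces distance, order and non-overlap", {
  w <- mk_exon("g", "g:A", 1000L, 1200L, "+")
  s <- mk_exon("g", "g:S", 3000L, 3100L, "+")
  p <- find_emats_pairs(w, s)
  expect_equal(nrow(p), 1L)
  expect_equal(p$distance_5p, 2000L)

  s_far <- mk_exon("g", "g:S", 6500L, 6600L, "+")
  expect_equal(nrow(find_emats_pairs(w, s_far)), 0L)

  # boundary: exactly 5000 nt is within range (inclusive)
  s_edge <- mk_exon("g", "g:S", 6000L, 6100L, "+")
  expect_equal(find_emats_pairs(w, s_edge)$distance_5p, 5000L)

  # reverse strand: 5' coordinates are the interval ends
  wm <- mk_exon("g", "g:A", 8000L, 8200L, "-")
  sm <- mk_exon("g", "g:S", 4000L, 4100L, "-")
  pm <- find_emats_pairs(wm, sm)
  expect_equal(pm$distance_5p, 4100L)

  # SE upstream of the AFE: no pair
  expect_equal(nrow(find_emats_pairs(mk_exon("g", "g:A", 8000L, 8200L, "+"),
                                     mk_exon("g", "g:S", 4000L, 4100L, "+"))), 0L)
  # overlapping exons: no pair
  expect_equal(nrow(find_emats_pairs(mk_exon("g", "g:A", 1000L, 1200L, "+"),
                                     mk_exon("g", "g:S", 1100L, 1300L, "+"))), 0L)
  expect_error(find_emats_pairs(w, mk_exon("g2", "g2:S", 3000L, 3100L, "+")),
               "single gene")
})

test_that("pairing agrees with a brute-force oracle on random configurations", {
  set.seed(21)
  for (rep in 1:40) {
    strand <- sample(c("+", "-"), 1)
    nw <- sample(1:3, 1); ns <- sample(1:3, 1)
    ws <- sort(sample.int(2e4, nw))
    ss <- sort(sample.int(2e4, ns))
    w <- mk_exon("g", paste0("g:A", 1:nw), ws, ws + sample(50:300, nw, TRUE), strand)
    s <- mk_exon("g", paste0("g:S", 1:ns), ss, ss + sample(50:300, ns, TRUE), strand)
    got <- find_emats_pairs(w, s)
    want <- oracle_pairs(w, s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) expect_setequal(got$distance_5p, as.integer(want[, 3]))
  }
})

test_that("pairs grow monotonically with the distance ceiling", {
  sim <- small_sim()
  sc5 <- emats_scan(sim$annotation, sim$junctions, sim$sample_map,
                    max_distance = 5000, per_tissue = FALSE)
  sc10 <- emats_scan(sim$annotation, sim$junctions, sim$sample_map,
                     max_distance = 10000, per_tissue = FALSE)
  key <- function(p) paste(p$gene_id, p$wafe_start, p$sse_start)
  expect_true(all(key(sc5$catalog$pairs) %in% key(sc10$catalog$pairs)))
  expect_gte(nrow(sc10$catalog$pairs), nrow(sc5$catalog$pairs))
})

test_that("the catalog cascade recovers exactly the planted genes", {
  sim <- small_sim()
  sc <- emats_scan(sim$annotation, sim$junctions, sim$sample_map,
                   per_tissue = FALSE)
  planted <- sim$truth$genes$gene_id[sim$truth$genes$is_emats]
  expect_setequal(sc$catalog$genes, planted)
  expect_true(all(diff(sc$catalog$cascade[1:6]) <= 0))
  # planted single-AFE genes never reach the >= 2 AFE stage
  single <- sim$truth$genes$gene_id[sim$truth$genes$gtype == "single_afe"]
  expect_false(any(single %in% sc$catalog$genes))
  # planted pair coordinates match
  tp <- sim$truth$pairs
  got <- sc$catalog$pairs[match(tp$gene_id, sc$catalog$pairs$gene_id), ]
  expect_equal(got$wafe_start, tp$wafe_start)
  expect_equal(got$sse_start, tp$sse_start)
  expect_equal(got$distance_5p, tp$distance)
})

test_that("the catalog is invariant under input row permutations", {
  sim <- small_sim()
  set.seed(33)
  ann2 <- sim$annotation
  ann2$exons <- ann2$exons[sample(nrow(ann2$exons)), ]
  ann2$genes <- ann2$genes[sample(nrow(ann2$genes)), ]
  jx2 <- sim$junctions[sample(nrow(sim$junctions)), ]
  sc1 <- emats_scan(sim$annotation, sim$junctions, sim$sample_map,
                    per_tissue = FALSE)
  sc2 <- emats_scan(ann2, jx2, sim$sample_map, per_tissue = FALSE)
  expect_equal(sc2$catalog$genes, sc1$catalog$genes)
  expect_equal(sc2$catalog$cascade, sc1$catalog$cascade)
})

test_that("build_catalog handles degenerate inputs", {
  genes <- data.frame(gene_id = character(), gene_type = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  meta <- data.frame(exon_id = character(), gene_id = character(),
                     chrom = character(), start = integer(), end = integer(),
                     strand = character(), is_alternative = logical(),
                     n_up = numeric(), n_down = numeric(), hit = numeric(),
                     role = character(), stringsAsFactors = FALSE)
  cat0 <- build_catalog(genes, meta, stats::setNames(numeric(0), character(0)),
                        stats::setNames(numeric(0), character(0)))
  expect_equal(length(cat0$genes), 0L)
  expect_equal(nrow(cat0$pairs), 0L)
  expect_error(build_catalog(genes, meta, c(ghost = 0.5),
                             stats::setNames(numeric(0), character(0))),
               "unknown event")
})

test_that("tissue-specific calling respects tissue groups", {
  cats <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("g4"))
  ts <- call_tissue_specific(cats)
  expect_equal(ts$A, "g1")
  expect_equal(ts$C, "g4")
  expect_false("g2" %in% unlist(ts))   # shared across groups: specific to none

  # brain sub-types grouped: a gene in both (and nowhere else) is brain-specific
  cats2 <- list(brain_cortex = c("g1", "g5"), brain_amygdala = c("g1"),
                testis = c("g2"))
  grouping <- c(brain_cortex = "brain", brain_amygdala = "brain",
                testis = "testis")
  ts2 <- call_tissue_specific(cats2, grouping)
  expect_setequal(ts2$brain, c("g1", "g5"))
  expect_equal(ts2$testis, "g2")
  # specific sets of distinct groups are disjoint
  expect_equal(length(intersect(ts2$brain, ts2$testis)), 0L)

  expect_error(call_tissue_specific(cats2, c(ghost_tissue = "x")), "unknown tissue")
  expect_error(call_tissue_specific(cats2[1]), "at least 2")
})

test_that("tissue overlap is the Jaccard index", {
  m <- tissue_overlap_matrix(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                                  C = c("a", "b", "c"), D = character(0)))
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["A", "C"], 1.0)
  expect_equal(m["A", "D"], 0.0)
  expect_equal(diag(m), c(A = 1, B = 1, C = 1, D = 0))
  expect_true(isSymmetric(m))
})

test_that("architecture summaries report lengths, roles and positions", {
  sim <- small_sim()
  sc <- emats_scan(sim$annotation, sim$junctions, sim$sample_map,
                   per_tissue = FALSE)
  arch <- summarize_architecture(sc$catalog, sc$annotation, sc$meta)
  expect_equal(nrow(arch$gene_lengths), nrow(sc$annotation$genes))
  expect_equal(sum(arch$gene_lengths$is_emats), length(sc$catalog$genes))
  expect_equal(arch$pct_fe + arch$pct_hfe, 100, tolerance = 1e-9)
  expect_true(all(arch$positions$dist_to_5p >= 0))
  expect_true(all(arch$positions$rel_position >= 0 &
                  arch$positions$rel_position <= 1))
  # wAFEs sit at the gene 5' end by construction, SEs further in
  expect_true(mean(arch$positions$dist_to_5p[arch$positions$class == "SE"]) >
              mean(arch$positions$dist_to_5p[arch$positions$class != "SE"]))
  expect_s3_class(arch$length_test, "htest")
})
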