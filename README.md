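# emats

Identification of human **EMATS** genes — *exon-mediated activation of
transcription starts* — and quantification of the splicing–transcription
coupling that defines them.

Efficient splicing of an internal exon can activate a weak promoter a few
kilobases upstream, so the inclusion level of that exon modulates the
gene's expression. Genes with this architecture are prime targets for
splice-switching therapeutics (small molecules, antisense
oligonucleotides) that raise gene expression by raising exon inclusion.
This package is for computational biologists who want to find such genes
in their own annotation + RNA-seq junction data, or to study the approach
itself on fully synthetic data with planted ground truth.

## What it computes

A gene is an EMATS gene when

1. it contains a **strong skipped exon** (sSE): median PSI across tissues
   above the median of all skipped-exon events,
2. it contains a **weak alternative first exon** (wAFE): median PSI below
   the median of all alternative-first-exon events, with ≥ 2 alternative
   first exons in the gene, and
3. wAFE and sSE do not overlap, the wAFE 5' coordinate lies
   transcriptionally upstream, and the two 5' coordinates are within
   5 kb.

Supporting machinery, each exposed as a documented function:

* meta-exon construction (strand-aware interval union of all annotated
  exons of a gene) and alternative/constitutive flagging;
* exon role calling from the splice-junction-read imbalance
  `hit = (n_down − n_up)/(n_down + n_up)` (first / internal / last /
  hybrid);
* PSI from junction counts — first-exon usage shares, and
  `PSI = (I/2)/((I/2) + skip)` for skipped exons;
* per-tissue catalogs, tissue-specific gene calling (with tissue
  groups), Jaccard overlap matrices, architecture summaries;
* pathogenic-variant filtering and strand-aware positional zones
  (upstream / TSS-or-3'ss / within exon / 5'ss / downstream) around
  EMATS exons, plus morbid-map merging;
* Spearman coupling of event PSI with host-gene TPM (≥ 70 pairs,
  constitutive observations dropped), gene-level merging, quantile
  binning, EMATS-vs-other Welch tests;
* RBP knock-down fraction tables and largest-residual selection;
* a synthetic-data generator (`emats_simulate()`) planting all of the
  above with known truth, and `run_pipeline()` tying every stage
  together deterministically.

## Worked example

```r
library(emats)

cfg  <- emats_sim_config(seed = 1)      # 200 genes, 5 tissues x 30 samples
sim  <- emats_simulate(cfg)
scan <- emats_scan(sim$annotation, sim$junctions, sim$sample_map)
scan
#> emats_scan: 200 genes, 1558 meta-exons, 5 tissues
#> EMATS catalog [inter-tissue]
#>   identification cascade:
#>     genes in                           200
#>     with skipped exon                  200
#>     with >=2 alternative first exons   158
#>     with weak AFE                      158
#>     with strong SE                     158
#>     EMATS genes                        30
#>     wAFE/sSE pairs                     30
#>   per-tissue catalogs: 5
```

The cascade mirrors the identification funnel: 200 protein-coding genes
in, all with a skipped exon, 158 with two or more alternative first
exons (the generator plants single-AFE genes as one violation class),
and 30 genes whose weak AFE sits within 5 kb upstream of a strong SE —
exactly the 30 planted EMATS genes (precision = recall = 1):

```r
head(scan$catalog$pairs[, c("gene_id", "wafe_id", "sse_id", "distance_5p",
                            "wafe_median_psi", "sse_median_psi")], 3)
#>   gene_id   wafe_id    sse_id distance_5p wafe_median_psi sse_median_psi
#> 1   G0010 G0010:ME1 G0010:ME4         725       0.1501978      0.7997184
#> 2   G0013 G0013:ME1 G0013:ME4        2311       0.1076820      0.8613603
#> 3   G0033 G0033:ME1 G0033:ME4         759       0.2013865      0.8140466
```

Each pair is a weak first exon (median PSI ≈ 0.10–0.20, i.e. a minor
promoter) a short distance upstream of a strongly included skipped exon
(median PSI ≈ 0.8–0.9). The planted coupling between inclusion and
expression is recovered by the Spearman machinery:

```r
recs <- coupling_records(scan$psi$se, sim$tpm,
                         sub(":ME.*", "", rownames(scan$psi$se)))
gr   <- merge_rho_gene_level(recs)
ie   <- gr$gene_id %in% scan$catalog$genes
res  <- compare_emats_vs_other(gr$rho[ie], gr$rho[!ie])
sprintf("mean rho EMATS %.2f vs other %.2f (p = %.2g %s)",
        res$mean_emats, res$mean_other, res$p, res$stars)
#> "mean rho EMATS 0.10 vs other 0.03 (p = 2.8e-06 *****)"
```

EMATS genes couple inclusion to expression more strongly than the rest —
the generator plants a steeper PSI→TPM slope for them, and the test
recovers it with five-star significance.

For real data, point `emats_scan()` at a GTF, a junction-count TSV
(`sample_id chrom strand donor acceptor count`, transcription-direction
boundary coordinates, 0-based half-open) and a sample→tissue map; see
`?emats_scan` and the methods vignette. A thin command-line wrapper
lives at `inst/cli/emats.R` (`simulate`, `scan`, `variants`,
`pipeline` subcommands).

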