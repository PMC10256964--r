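---
title: "Identifying EMATS genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying EMATS genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The phenomenon and the catalog criteria

Exon-mediated activation of transcription starts (EMATS) is a coupling
between splicing and transcription: efficient splicing of an internal
exon can activate a weak promoter located a short genomic distance
upstream, so that changing the inclusion of the exon changes the
gene's expression. A gene has the *EMATS architecture* when three
criteria hold simultaneously:

1. the gene contains a highly included ("strong") skipped exon (sSE) —
   its median percent-spliced-in (PSI) across tissues lies above the
   median of all skipped-exon events;
2. the gene contains a weakly used alternative first exon (wAFE) — its
   median PSI lies below the median of all alternative-first-exon
   events — and at least two alternative first exons overall, so that
   promoter choice is actually variable;
3. the wAFE and the sSE do not overlap, the wAFE 5' coordinate is
   transcriptionally upstream of the sSE 5' coordinate, and the two 5'
   coordinates are within 5 kb (inclusive).

`emats_scan()` applies this cascade to a gene annotation plus
per-sample splice-junction read (SJR) counts, both across all tissues
and per tissue; tissue-specific EMATS genes are those identified in
one tissue (or one tissue group, e.g. all brain sub-types) and no
others.

## Coordinates

Everything internal is 0-based, half-open `[start, end)` on an
explicit strand, the convention of BED and of the architecture
formulas: gene kilobase length is `(end - start) / 1000`, and an
exon's distance to its host gene's 5' coordinate is
`exon_start - gene_start` on `+` and `gene_end - exon_end` on `-`.
GTF input (1-based, closed) is converted at the I/O boundary only.
A consequence taken literally throughout: two exons that share only a
boundary coordinate ("bookended") do **not** overlap and are not
merged into one meta-exon.

## Meta-exons and exon roles

All overlapping exons of a gene, across its transcripts, are collapsed
into *meta-exons* (interval union via `IRanges::reduce` with
`min.gapwidth = 0`, so only a ≥ 1 nt overlap merges). A meta-exon is
*alternative* when at least one transcript of the gene has no exon
overlapping it; overlap rather than exact identity is used because
meta-exons absorb alternative splice sites.

Roles come from the pooled SJR profile of each meta-exon. With `n_up`
the reads spliced *into* the exon's 5' boundary and `n_down` the reads
spliced *out of* its 3' boundary, the downstream imbalance is

```
hit = (n_down - n_up) / (n_down + n_up)   in [-1, 1]
```

`hit ≥ 0.8` calls a first exon, `hit ≤ -0.8` a last exon,
`|hit| ≤ 0.2` an internal exon, and anything in between a hybrid exon
(positive side: hybrid first/internal, which still qualifies as an AFE
candidate). Exons with fewer than 10 pooled junction reads stay
unclassified, and only annotated meta-exons are ever classified. The
three thresholds (`t_terminal = 0.8`, `t_internal = 0.2`,
`min_reads = 10`) are deliberate simplifications of a full generative
hybrid-internal-terminal model: the ratio is the direct formalization
of "downstream SJR imbalance", and the defaults put the cut points
well away from both the pure-terminal (±1) and balanced (0) profiles.
All three are arguments of `emats_scan()`.

## PSI quantification

*First-exon usage* (AFE PSI): per sample, an AFE's PSI is its share of
`n_down` among the gene's first (and hybrid-first) exons. Shares sum
to 1 within a gene whenever the gene has first-exon coverage in the
sample and are missing — never zero — when it has none.

*Skipped-exon PSI*: with inclusion reads `I = inclusion_up +
inclusion_down` and `skip` reads whose intron fully contains the exon,

```
PSI = (I/2) / (I/2 + skip)
```

Inclusion is supported by two junctions and skipping by one, hence the
effective lengths 2 and 1; PSI is undefined when `I + skip = 0`.

*Across-tissue aggregation*: mean of defined per-sample values within
each tissue, then the median over tissues (configurable to a pooled
median). Missing values propagate as missing at every step.

*Strength calls*: within each event class the threshold is the median
of all events' across-tissue median PSI; strictly below is weak,
strictly above strong, exactly equal neither. The strict inequalities
make the degenerate all-identical class yield all-"neither" rather
than an arbitrary split.

## Variant zones

Each catalog exon tiles its ±1000 nt flank into five strand-aware
zones: upstream, acceptor-side window (25 nt; the TSS-proximal region
of an AFE, the 3' splice site of an SE), within-exon, donor-side
window (6 nt; the 5' splice site), downstream. Window widths follow
the canonical splice-site motif extents (the 3' splice-site
polypyrimidine tract/branch region versus the compact 5' splice-site
motif); all three are configurable. The five windows partition every
offset in the flank exactly once — a property the test suite checks
exhaustively over random geometries. Variants are kept when their
clinical significance contains "pathogenic" but not "conflicting"
(case-insensitive), and disease annotations come from an inner join
with a morbid-map-style gene-phenotype table before the positional
intersection.

## Splicing-expression coupling

Per event, observations with PSI exactly 0 or 1 are dropped (the
constitutive rule read per observation; a flag switches to dropping
whole constitutively-flat events instead), and Spearman's rho against
host-gene TPM is computed only when at least 70 pairs survive. Event
rho values merge to gene level by arithmetic mean (flag: median); the
70-pair floor and the mean were chosen as the most literal and the
most common readings respectively, and both alternatives remain one
argument away. Group comparisons use the two-sided Welch t-test —
independence is all that is claimed for the samples, so the
unequal-variance form is the robust default.

RBP knock-down experiments are summarized as fractions of
significantly (adjusted p strictly < 0.05) up/down regulated genes and
skipped exons over the totals each differential tool reported. The
differential-gene fraction is regressed on the differential-SE
fraction per direction; the union of the top-17 absolute residuals per
direction (ties, including the all-collinear degenerate case, broken
by RBP name for determinism) marks the RBPs whose expression effect is
out of proportion to their splicing effect.

## The synthetic-data generator

`emats_simulate()` builds a complete, self-consistent dataset with
planted truth. Each protein-coding gene follows one transcription-order
layout — AFE1, AFE2, C1, SEf, C2, SEb, C3, L — where AFE1/AFE2 are
alternative first exons, SEf is the focal skipped exon placed a drawn
distance `d` downstream of AFE1's 5' coordinate, C* are constitutive
internal exons and L the last exon. Genes alternate chromosomes and
strands. Junction reads are molecule flows: per gene and sample a
Poisson(depth) number of molecules choose a first exon by the planted
usage and include SEf/SEb binomially at the planted per-tissue PSI;
every junction on a molecule's path contributes one read, which makes
the emitted counts exactly consistent with the annotation coordinates
and the planted PSI. `noise = FALSE` replaces sampling with rounded
expected flows.

Planted PSI values per tissue come from truncated Betas: weak events
from Beta(2, 6) restricted to (0, 0.35], strong events from Beta(8, 2)
restricted to [0.65, 1). Two design points deserve explanation:

* **The balancer exon.** Strength is *relative* — weak means below the
  realized class median. A planted label can only be guaranteed to
  match the relative call if each event class is balanced around the
  gap between the clusters, so every gene carries a second alternative
  internal exon (SEb) of the *opposite* strength, placed > 5 kb from
  every first-exon 5' coordinate so it can never form a pair. Each
  gene then contributes one weak and one strong skipped-exon event,
  the class median always falls inside the (0.35, 0.65) gap, and
  planted labels equal relative calls deterministically. The two AFE
  usage shares (u and 1 − u, truncated the same way) balance the AFE
  class for free.
* **The "strong AFE" violation class.** With first-exon usages summing
  to one, a two-AFE gene always has one AFE below the class median, so
  "the gene has no weak AFE" cannot be planted literally. The class is
  realized as: the only AFE within pairing range of the strong SE is
  the strong one, with the weak AFE placed just beyond 5 kb
  (d ∈ (5020, 5170], second AFE 300 nt further in). The other three
  violation classes are literal: distance (d ∈ (6000, 9000)), weak
  focal SE, and a single constitutive first exon.

A configurable fraction of genes (default 0.3) also receives a
"bridge" isoform that splices from AFE1 into AFE2, giving AFE2 a
hybrid first/internal profile; the planted AFE PSI values account for
the bridged flow analytically.

Expression follows `log2 TPM = β0 + β1 · PSI(SEf, tissue) + N(0, σ)`
with β1 = 2 for EMATS genes and 0.5 otherwise (σ = 0.5), emulating a
positive inclusion-expression coupling that is steeper for EMATS
genes. Variants draw a zone from the configured mix, a position
uniformly within that zone's window, and a significance label that is
(likely) pathogenic with probability 0.6. RBP fraction tables sit on a
planted line (intercept 0.02, slope 1.2, σ = 0.005) with five points
displaced by 0.08 — sixteen residual standard deviations, so recovery
is expected to be exact.

Default cohort shape: 200 genes (15% EMATS), 5 tissues (two of them
brain sub-types sharing the "brain" group) × 30 samples, mean junction
depth 300. All randomness flows from one master seed through named
sub-streams (annotation, psi, junctions, expression, variants, rbp),
so adding or re-running one generator never perturbs another, and a
fixed seed reproduces every output byte for byte.

### What the generator does and does not emulate

It emulates the statistical structure the pipeline consumes:
multi-transcript genes with alternative first exons and skipped exons
on both strands, junction counts binomially consistent with planted
PSI, tissue structure, a PSI-dependent expression trend that is
stronger for EMATS genes, zone-distributed variants and RBP fraction
tables with planted outliers. It does **not** emulate realistic
exon/intron length distributions, overlapping or nested genes,
unannotated exons, alternative 5'/3' splice sites within a meta-exon,
read-level artifacts (mapping bias, library-size variation), linkage
between variants, or a gene-length difference between EMATS and other
genes. Passing the planted-recovery tests therefore demonstrates the
correctness of the interval arithmetic, the PSI estimators and the
criteria cascade under the stated noise model — not robustness to
annotation incompleteness or alignment artifacts in real data.

## Numerical choices and degenerate inputs

* Undefined PSI (no coverage) is `NA` and never 0; events whose
  across-tissue median is `NA` are excluded from strength calling.
* `hit` is undefined at zero coverage; exons below `min_reads` are
  "unclassified" and take no further part.
* The 5 kb pairing rule is inclusive (`distance_5p <= 5000`), distances
  are measured between transcription-direction 5' coordinates, and
  "upstream" is enforced strictly.
* Quantile binning ranks with `ties.method = "first"` so bin sizes are
  as equal as possible; an all-identical vector errors by default
  (flag: one bin).
* Jaccard overlap of two empty tissue sets is reported as 0; the
  diagonal is 1 only for non-empty sets.
* Junction boundary keys are formatted as integers, so coordinates
  near powers of ten can never fall into scientific notation and miss
  their exonic counterparts.

## Problem sizes used by the test suite

The suite regenerates everything programmatically: planted recovery
runs at the full study shape (200 genes, 5 × 30 samples) both
noise-free and noisy; the union oracle runs 1000 random interval sets
(≤ 50 intervals, coordinates < 1e5); the Spearman oracle 100 random
vector pairs (n = 100, tolerance 1e-12); zone partitioning 100 random
geometries; estimator accuracy 30 genes at depth 1000 (mean absolute
error < 0.02); determinism two full pipeline runs. `sessionInfo()`
level reproducibility comes from the single-seed design rather than
from stored fixtures.

## Known limitations

* The exon-role classifier is a single imbalance statistic, not a
  generative model; exons with genuinely mixed terminal/internal usage
  near the thresholds can flip between hybrid and first/internal under
  resampling.
* AFE PSI is defined through downstream-junction shares, so first
  exons of single-exon transcripts (no junction) are invisible to it.
* Tissue-specific calling compares gene *sets*; it does not test
  whether the underlying PSI difference between tissues is
  statistically significant.
* The Spearman p-value is not computed; the package reports rho and
  pair counts and leaves inference to the group-level comparison.
* Catalog results depend on the annotation's transcript completeness,
  exactly as the meta-exon construction does.
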