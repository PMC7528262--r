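# cnvpop

Comparative copy-number-variation (CNV) analysis between two cattle
populations — typically the taurine (*Bos taurus*) and indicine
(*Bos indicus*) subspecies — from per-animal calls produced by two
complementary CNV callers.

## Who this is for

Population and livestock genomicists who have run, per animal, both

* a **boundary-resolution structural-variant caller** (split-read /
  paired-end, LUMPY-style VCF with `SVTYPE=DEL/DUP` and `END`), giving
  single-base CNV boundaries, and
* a **read-depth caller** (CNVnator-style text:
  `type chrom:start-end size normalized_RD ...`), giving the copy number,

and want to turn those calls into population-level objects: confident
calls, CNV regions (CNVRs), boundary-consistent CNV segments, a
five-class genotype matrix, and a ranked list of lineage-differential
segments.

## The model

1. **Confident calls.** A boundary-caller call is kept when a depth-caller
   call of the same type (loss/gain) overlaps it (default: any ≥ 1 bp
   overlap). The confident interval is the boundary caller's verbatim; the
   copy-number class is `clamp(round(2·RD), 0, 4)` from the overlapping
   depth call with the largest overlap, where RD ≈ 1 is diploid and class 4
   encodes "≥ 4".
2. **CNVRs.** Distinct CNVs (identical coordinates + type across animals)
   are merged single-linkage by ≥ 1 bp overlap, type-blind
   (loss/gain/mixed recorded); regions supported by < 4 animals are
   discarded.
3. **Segments.** Within each CNVR, the union of member-call breakpoints
   dissects the region into segments with identical boundaries in every
   animal; segments ≤ 50 bp are dropped. Each animal is genotyped per
   segment into classes {0, 1, 2, 3, ≥4} (2 = diploid default; a class is
   assigned when a confident call fully contains the segment).
4. **Differentiation.** Per segment, with genotype-class frequencies `x_i`,
   `y_i` over `N_x`, `N_y` individuals:

       t_i  = (x_i·N_x + y_i·N_y) / (N_x + N_y)
       H_t  = 1 − Σ t_i²
       H_s  = ((1 − Σ x_i²)·N_x + (1 − Σ y_i²)·N_y) / (N_x + N_y)
       F_ST = (H_t − H_s) / H_t        (0 when H_t = 0)

   Segments in the top 1% (or 0.1%) of F_ST are the candidate
   lineage-differential CNVs; ties at the cut are kept.
5. **Annotation.** Gene/exon overlap (≥ 1 bp), feature-class
   observed/expected enrichment, 1-Mb window CNV density with clusters
   (> 80% covered, strict), breed/subspecies sharing, and
   subspecies-specific sequence filtering (coverage runs > 500 bp at depth
   ≥ 2).

A synthetic-cohort generator (`sim_config()` / `simulate_cnv_cohort()`)
emulates the two-subspecies, multi-breed design with known truth —
planted shared, background and fixed-deletion differential events,
between-caller boundary jitter, and class-preserving depth noise — so the
whole pipeline is testable without external data.

## Worked example

```r
library(cnvpop)

cfg <- sim_config(seed = 42)                 # 5 x 10 Mb, 2 subspecies x 2 breeds x 5 animals
sim <- simulate_cnv_cohort(cfg, "simdata")   # writes VCFs, depth text, sheet, sizes, truth
res <- run_cnv_pipeline("simdata", min_support = 4, min_len = 50)

fst <- fst_scan(res$genotypes, res$sample_table,
                pop_x = "taurine", pop_y = "indicine")
rank_segments(fst, 0.001)[1:3, c("segment_id", "Ht", "Hs", "fst", "rank")]
```

which prints (the planted fixed-deletion segment is recovered at rank 1
with F_ST = 1):

```
confident calls: 56343 | distinct CNVs: 12201 | CNVRs: 4448 | segments: 16907

             segment_id    Ht    Hs       fst  rank
1: chr1:2861395-2866206 0.500  0.00 1.0000000     1
2: chr1:1182992-1184590 0.455  0.21 0.5384615     2
3: chr3:8868412-8868727 0.455  0.21 0.5384615     3
```

Row 1 is the segment deleted in every indicine animal and diploid in every
taurine one: the pooled class frequencies are fixed-and-opposite, so
`H_s = 0`, `H_t = 0.5` and `F_ST = 1`. Background private CNVs produce the
low-F_ST tail. `subspecies_comparison(res$cnvrs, res$sample_table)` on the
same run reports 98.38% of CNVRs shared between subspecies — shared and
background events are planted across both populations, so only
low-carrier regions end up subspecies-specific at this simulation scale.

A thin CLI over the same functions lives at
`system.file("cli", "cnvpop.R", package = "cnvpop")`
(`simulate`, `integrate`, `cnvr`, `segment`, `fst` subcommands).

## Documentation

The methods vignette (`vignettes/cnv-population-comparison.Rmd`) documents
the model, every tunable threshold and its boundary semantics, the
synthetic-data design, numerical tie-break rules, and known limitations.
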