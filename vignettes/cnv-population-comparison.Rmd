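---
title: "Comparing copy-number variation between two populations with cnvpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing copy-number variation between two populations with cnvpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
library(data.table)
```

## The problem

Copy-number variants called from short-read data by a single algorithm are
noisy: read-depth (RD) callers estimate the copy number well but smear
boundaries to the bin size, while split-read/paired-end (SR/PEM) callers
resolve breakpoints to the base but say little about the resulting copy
count. `cnvpop` implements the integration strategy used in comparative
cattle genomics: keep only calls corroborated by **both** strategies, take
the **interval** from the boundary caller and the **copy number** from the
depth caller, and build population-level objects from those confident
calls — CNV regions (CNVRs), boundary-consistent CNV segments, a
segment × animal genotype matrix over the classes {0, 1, 2, 3, ≥4}, and a
per-segment F~ST~ between two populations (canonically the taurine and
indicine cattle subspecies).

## Pipeline stages and their parameters

### Call integration

`intersect_calls()` pairs one sample's boundary-caller calls with its
depth-caller calls.

* `min_overlap_bp = 1`, `reciprocal_fraction = 0` — the corroboration rule
  is "same type in both callers"; no overlap fraction is imposed by
  default because none is part of the method's definition. A reciprocal
  fraction is available for stricter studies.
* Copy class: `clamp(round_half_up(2·RD), 0, 4)`, RD = normalised read
  depth (1.0 ≈ diploid), class 4 encoding "≥4". Half-up rounding is used
  deliberately: R's banker's rounding would map RD = 0.25 to class 0 or 1
  depending on parity, which is not reproducible across implementations.
* When a boundary call overlaps several same-type depth calls, the largest
  overlap wins; ties resolve by the smallest symmetric difference with the
  boundary call, then by the leftmost depth call. The tie-break is chosen
  so an exactly coextensive depth call always wins, and the rest is
  determinism for its own sake.
* The class is forced consistent with the call type (loss → class ≤ 1,
  gain → class ≥ 3). The two callers have already agreed on the type; a
  depth value that rounds to diploid is treated as attenuated signal of
  the typed event rather than evidence against it. Without this rule a
  "confident loss at class 2" would be representable, which the genotype
  model cannot express.

### CNVRs

`collapse_distinct()` deduplicates identical (chrom, start, end, type)
calls across animals; `build_cnvrs()` merges distinct CNVs single-linkage
by ≥ 1 bp overlap. Merging is **type-blind** (regions may be loss, gain or
mixed) because a region's identity is positional; the mixture is recorded
in `region_type`. Half-open intervals that merely touch (`end == start`)
share no base and do not merge. Regions supported by fewer than
`min_support = 4` distinct animals are discarded; support counts animals
contributing *any* member CNV, not animals spanning the whole region.

### Segments and genotypes

`dissect_segments()` pools every member call's start/end inside a CNVR,
sorts them, and emits the intervals between consecutive breakpoints that
are covered by at least one call. Because the breakpoints are the union
across all animals, every animal is genotyped over identical intervals.
The length filter is **strict**: segments must exceed 50 bp, so a 50 bp
segment is dropped. Gaps inside a CNVR covered by no call yield no
segment.

`genotype_segments()` assigns a sample's class at a segment from a
confident call that **fully contains** the segment; partial overlap (only
possible for calls that did not contribute the local breakpoints) never
assigns a genotype, keeping the matrix well defined. Samples with no
containing call are diploid (class 2). Conflicting containing calls from
one sample resolve to the class farthest from 2 (the most extreme event),
ties to the lower class — a deterministic rule for a case the method's
definition leaves open; conflicts are counted and reported.

### F~ST~ on genotype classes

`compute_fst()` / `fst_scan()` implement the genotype-class form

$$t_i = \frac{x_i N_x + y_i N_y}{N_x + N_y},\qquad
H_t = 1 - \sum_i t_i^2,\qquad
H_s = \frac{(1-\sum_i x_i^2)N_x + (1-\sum_i y_i^2)N_y}{N_x + N_y},\qquad
F_{ST} = \frac{H_t - H_s}{H_t}$$

where $x_i, y_i$ are the proportions of individuals in each population
carrying genotype class $i$. Three numerical choices:

* The class set is the five classes {0, 1, 2, 3, ≥4}; a six-label
  enumeration ("A4 or > A4") sometimes seen for this statistic is treated
  as notation for the same five classes with the top two collapsed.
* $H_t = 0$ (both populations fixed for the same class) defines
  $F_{ST} = 0$: no divergence is measurable where there is no diversity.
* Frequencies are **individual-genotype** frequencies, pooled across
  breeds within a subspecies, not chromosome-allele frequencies — CNV
  genotypes here are unphased integer classes, so an allelic
  decomposition would be arbitrary.

For equal-sized populations the identity
$H_t - H_s = \tfrac14\sum_i (x_i - y_i)^2$ makes the bounds
$0 \le F_{ST} \le 1$, the symmetry, and "zero iff identical frequencies"
exact; the test suite verifies all three over randomized frequency pairs,
plus monotonicity along a fixation gradient.

`rank_segments()` returns the `ceiling(f·n)` highest-F~ST~ segments at
`top_fraction = f` and **includes ties at the cut** rather than breaking
them arbitrarily — reproducibility is preferred over returning an exact
count.

### Annotation summaries

* `overlap_genes()`: a gene is affected by a ≥ 1 bp overlap between any of
  its features and any CNVR (inclusive bound; book-ended intervals do not
  overlap). Exon-affected genes are the subset with exonic overlap.
* `feature_class_enrichment()`: observed = fraction of total CNVR bp in
  the class's interval union; expected = fraction of the autosomal genome
  the class covers; O/E = ratio. A length-fraction null is used rather
  than permutation — the statistic is descriptive, and a permutation mode
  is out of scope.
* `window_density()` / `detect_clusters()`: non-overlapping 1-Mb windows;
  the terminal window of each chromosome keeps its true (shorter) length
  as denominator. A window belongs to a cluster when its covered fraction
  **strictly** exceeds 0.80; adjacent qualifying windows merge into one
  cluster region.
* `subspecies_comparison()` partitions CNVRs into shared /
  taurine-specific / indicine-specific by the subspecies of their
  supporting samples and reports the shared percentage to two decimals.
  "Shared by all breeds" (`shared_by_all()`) requires every breed, not
  every animal, to contribute at least one supporter.
* `specific_sequences()` (subspecies-specific sequence filter): keep
  coverage ≥ 2 (inclusive), merge adjacent and book-ended runs, keep
  merged runs **strictly** longer than 500 bp.

### Coordinates

Everything internal is 0-based half-open. VCF `POS` and CNVnator-style
`chrom:start-end` (both 1-based inclusive) are converted at ingest, BED
and bedGraph pass through unchanged, and segment/CNVR identifiers
(`chrom:start-end`) are printed in the internal convention. Caller
vocabulary (DEL/DUP, deletion/duplication) is normalised to loss/gain at
the boundary.

## The synthetic cohort

`simulate_cnv_cohort()` generates the *stated world* the test suite runs
in: a 5 × 10 Mb genome; two subspecies × two breeds × five animals (20
animals); 12,000 background CNVs with log-uniform lengths 500–10,000 bp
carried by 1–8 random animals; 200 breed-shared events carried by each
animal with probability 0.5 (minimum 4 carriers, so shared regions always
survive the support filter); and one lineage-differential fixed-deletion
segment (loss frequency 0 in taurine, 1 in indicine). Event classes are
drawn from {0, 1, 3, 4} with losses weighted 2:1 over gains, reflecting
the deletion excess typical of short-read CNV surveys; class 2 is reserved
for non-carriers.

Design choices worth knowing:

* **Jitter is asymmetric by construction.** Boundary-caller calls carry
  the exact planted interval; only the depth caller's endpoints are
  jittered (rounded normal, sd 20 bp by default, truncated to preserve
  ≥ 1 bp overlap). This mirrors why the boundary caller's interval is
  taken verbatim downstream, and makes zero-jitter recovery an exact
  identity test.
* **Depth noise is class-preserving.** RD = class/2 + noise with the
  noise clamped to ±0.24, so `round_half_up(2·RD)` always returns the
  planted class. Without the clamp, recovery tests would be flaky by
  design rather than diagnostic.
* **Differential segments are kept clear** of all other planted events
  (rejection sampling), so the planted interval survives dissection as a
  single segment and its F~ST~ is not diluted by overlapping background.
  Background events may overlap each other freely, which is what produces
  multi-segment CNVRs.
* The event count was sized so the default world yields > 10,000
  segments after the support and length filters (about 17,000 in
  practice), large enough for percentile-ranking behaviour to be tested
  meaningfully.

What the generator does **not** emulate: read-level noise (no FASTQ/BAM),
caller false positives/negatives, type disagreement between callers,
reference bias, or linkage between events. A green end-to-end test
therefore establishes that the pipeline's arithmetic is faithful, not that
the callers themselves are accurate on real data.

## Scaling of the test suite

The brute-force oracles (per-base bitmaps, union-find closure, per-segment
truth genotyping) are intentionally naive, so the suites that use them run
on reduced instances: per-base equivalence on ≤ 100 kb chromosomes, and
the zero-jitter exact-recovery check on a 1,200-background-event world.
The full 12,000-event stated world is exercised in the jittered
end-to-end acceptance test, where only vectorised code paths run.

## Known limitations

* Genotype classes are capped at "≥ 4"; high-amplification loci are not
  distinguished beyond class 4.
* F~ST~ pools individuals within a population; breeds are not weighted
  equally, so unbalanced panels tilt the statistic toward the larger
  breed.
* No permutation p-values accompany the percentile ranking; the top-x%
  cut is a screening device, not a significance statement.
* `pca_coordinates()` is plumbing for cohort visualisation (deterministic
  up to axis sign); admixture/structure estimation and clustering are out
  of scope.
* The subspecies-specific-sequence filter summarises externally produced
  remapped-read coverage (bedGraph); alignment itself is out of scope.
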