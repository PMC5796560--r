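---
title: "Calling mobile element insertions from targeted paired-end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mobile element insertions from targeted paired-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teclust)
```

## The problem

A handful of transposable element (TE) subfamilies — the LINE-1
subfamily L1HS and the Alu subfamilies AluYa5/8 and AluYb8/9 — are
still mobile in the human genome. New insertions segregate between
individuals, occasionally arise de novo, and are invisible to standard
SNP genotyping. Whole-genome sequencing finds them, but at a high cost
per informative read: active-TE junctions are a vanishing fraction of a
full library.

`teclust` implements the computational half of a *targeted* approach.
The wet-lab protocol enriches, per subfamily, for fragments that span
the 3' junction between a TE copy and its unique genomic flank.
Sequenced as a read pair:

* **read 2** begins at a subfamily-diagnostic *nested primer*, continues
  through a short stretch of diagnostic TE sequence (the *TE-like*
  region), the poly-A tail of the element, and finally into genomic
  flank;
* **read 1** is sequenced from the other end of the fragment and lies
  entirely in unique flank, so it aligns confidently and *anchors* the
  insertion to a genomic coordinate.

Everything downstream follows from this asymmetry: read 2 proves the
fragment came from a target TE, read 1 says where the TE is.

## The pipeline

The pipeline consumes coordinate-sorted, duplicate-marked alignments
(one SAM/BAM per sample-by-subfamily library) and proceeds in four
stages. All stages are pure functions over data frames, orchestrated by
`run_call()`.

### 1. Read-pair filtering (`filter_pairs()`)

Each pair is kept or dropped for exactly one reason, tested in a fixed
order so that the per-reason tallies sum to the input count:

1. `DUPLICATE` — PCR/optical duplicate flag.
2. `NO_PRIMER` / `PARTIAL_PRIMER` — read 2 must begin with the nested
   primer. A full prefix match is `FULL`; at least 7 matches over the
   first 10 bases is `PARTIAL` (kept, tallied separately — likely
   on-target with sequencing error); fewer is genomic background and
   dropped.
3. `TE_LIKE_UNCOVERED` / `TE_LIKE_EXCEEDED` — the bases following the
   primer are compared to the subfamily's TE-like sequence over the
   positions the read actually covers. More mismatches than the
   subfamily cap (3 for L1HS over 8 nt; 10 for the Alu libraries over
   37/29 nt) indicates an inactive, diverged TE copy and drops the
   pair. Reads too short to cover any TE-like base get their own
   reason rather than a silent pass.
4. `READ1_UNMAPPED` / `MAPQ_ZERO` — without a confidently mapped
   read-1 anchor there is nothing to cluster; MAPQ 0 means the aligner
   saw multiple equally good placements.

Presence of a poly-A run (default: ≥8 bases with at most 1 non-A,
scanned downstream of the TE-like region) is recorded as corroborating
evidence but is deliberately *not* a drop criterion: the poly-A may
simply lie beyond the read end.

### 2. Clustering (`cluster_reads()`, `apply_cluster_thresholds()`, `apply_mask()`)

Kept read-1 anchors are clustered per library and chromosome by
single linkage on start position: adjacent sorted reads at most 200 bp
apart join one cluster, so any two retained clusters are separated by
more than 200 bp. A cluster becomes a candidate insertion when it has
at least 2 members at MAPQ ≥ 3 and its interval spans at least 100 bp
(one full read footprint passes; degenerate micro-clusters of clipped
alignments do not). Lower-MAPQ members (≥1) still count toward totals
and span.

Candidates are then screened against a genome accessibility mask:
assembly gaps widened by 500 bp, satellite-enriched regions
(centromeres/telomeres) widened by 1 Mb, and chrY excluded outright
(targeted TE data from it is dominated by its extreme repeat content).
Masked clusters are not discarded silently — they are returned as an
audit table with the mask reason.

### 3. Classification (`classify_clusters()`)

Each candidate is compared, within a 600 bp window, to the 3' terminal
position of known TE copies — interval end for a plus-strand
annotation, start for minus-strand, both ends when the strand is
unknown. The 3' end is the right reference point because the assay
reads outward from the element's 3' junction. Status is assigned in
priority order:

* **reference** — a reference-genome TE annotation of the library's
  own subfamily (synonyms honoured, e.g. AluYa5 and AluYa8 for the
  AluYa5/8 library) has its 3' anchor within the window;
* **known non-reference** — failing that, a polymorphic-TE database
  record of the library's TE *class* is within the window. Class-level
  matching reflects those databases' frequently missing subfamily
  designations;
* **novel** — otherwise: a putative new insertion.

Within a stage the closest record wins, ties broken by record id.
Calls are written as TSV (round-trippable via `read_calls()`) and BED
(0-based half-open, per the format's convention).

### 4. Evaluation (`run_evaluate()`)

`match_calls_to_truth()` matches calls to a truth set greedily,
one-to-one, by increasing distance within the 600 bp window — a single
call can never satisfy two truth records, preventing double counting.
Recall = TP/(TP+FN), precision = TP/(TP+FP); a metric with a zero
denominator is reported as undefined (`NaN` with a `*_defined` flag),
never silently as 0 or 1.

Three specialised modes:

* **trio** — the parental truth set is the loci detected in *both*
  parents (clusters matched within 100 bp). A proband novel call is
  counted *inherited* if either parent shows even a single kept read
  within 100 bp — thresholds bypassed, because essentially every real
  insertion leaves at least one read — and *de novo* only when both
  parents are empty there. De novo calls are treated as false
  positives for precision, a deliberately conservative stance given
  how rare true de novo insertions are.
* **longread** — a call is validated when at least one long read fully
  spans the cluster interval and contains the subfamily's TE-like
  sequence exactly, in either orientation.
* **sweep** — `sweep_read_depth()` recomputes precision/recall while
  sweeping the minimum read support. Raising the threshold can only
  drop calls, so recall is non-increasing; low-support spurious
  clusters disappear first, so precision is non-decreasing where
  defined.

## Primer-site genomics (`scan_primer()` and friends)

The package also covers the genomic side of assay design.
`scan_primer()` finds primer annealing sites on both strands of a
reference sequence, allowing 1 mismatch but requiring the 3'-ultimate
base to match exactly (a 3' mismatch blocks polymerase extension) and
rejecting windows containing N. `build_target_set()` pairs
target-primer and nested-primer sites in proper order and orientation
within 200 bp to enumerate expected reference loci.
`find_inverted_repeats()` flags head-to-head site pairs within 1 kb —
loci where amplification can proceed from both sides and produce
artifact read pairs whose read 1 typically maps with MAPQ 0 (the
filter already drops these; the scan explains *why* they exist).
`derive_te_like()` extracts the TE-like region from a subfamily
consensus by stripping the nested primer and the terminal poly-A run.

The shipped `te_profiles()` sequences are synthetic stand-ins with the
correct geometry (8/37/29 nt TE-like regions, caps 3/10/10); real
assay oligos can be supplied through `te_profile()`.

## The simulator (`simulate_genome_and_insertions()`, `simulate_library()`)

The simulator provides planted ground truth for end-to-end
verification. Each targeted subfamily gets its own random chromosome
(default 100 kb) carrying 10 *reference* insertions (present in the
simulated reference and donor) and 10 *non-reference* insertions
(donor only), spaced ≥2 kb so clusters from distinct loci can never
merge. Each planted element is the profile consensus: target primer,
nested primer, TE-like sequence, poly-A tail.

Per locus, fragments are drawn from a normal length model
(300 ± 30 bp) and sequenced as 151 bp pairs with the exact read
architecture described above. Alignments are emitted directly at their
true coordinates rather than through an aligner: read 1 maps
minus-strand at MAPQ 60; read 2 from a reference locus maps at the
planted TE with MAPQ 0–5 (a repeat copy aligns ambiguously), and from
a non-reference locus is unmapped (its element is absent from the
reference). Background pairs (random read 2 — no primer) and
head-to-head artifact pairs (primer-bearing read 2, read-1 MAPQ 0) are
mixed in at configurable fractions, 30% and 2% by default. All
randomness flows from a single seed; identical configuration gives
byte-identical output, and `write_fixture()` round-trips through plain
SAM/FASTQ/FASTA/BED.

With default settings (no sequencing error, 10 fragments/locus) the
pipeline must recover every planted insertion with no false positives
— recall and precision exactly 1.0 — which is asserted in the test
suite, alongside brute-force oracle equivalences for clustering,
primer scanning and truth matching.

## Design decisions and limitations

* **Coordinates are 1-based and closed internally**, the
  R/Bioconductor convention (GRanges, IRanges, `matchPattern`);
  BED's 0-based half-open convention applies at file boundaries only.
  Mixing conventions inside the code is the classic source of
  off-by-one errors.
* **Filter reasons are exclusive and ordered**, so per-reason counts
  always sum to the input pair count — an invariant the tests enforce
  on every run.
* **Simulated MAPQ is a caricature** (60 for unique, 0–5 for
  repetitive); it exercises the pipeline's thresholds but does not
  model aligner-specific MAPQ distributions.
* The simulator plants full consensus junctions only: no 5'
  truncations, inversions, or transductions, and no indel sequencing
  errors (substitutions only).
* Long-read validation automates only the exact-substring rule;
  judging clipped or rearranged long-read alignments is left to manual
  review.
* Problem sizes are desk-scale by design: chromosome-sized references
  and million-read libraries would pass through the same code paths
  but have not been profiled here.
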