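# teclust

Detection of active transposable element (TE) insertions — L1HS,
AluYa5/8 and AluYb8/9 — from targeted paired-end sequencing.

A few TE subfamilies still copy themselves around the human genome.
Their new insertions differ between individuals and occasionally arise
de novo, but finding them by whole-genome sequencing is wasteful:
informative junction fragments are a tiny fraction of a library. In the
targeted design this package supports, each library is enriched for
fragments spanning the 3' junction of one active subfamily. Read 2 of a
pair starts at a subfamily-diagnostic nested primer and runs through
diagnostic TE sequence and the element's poly-A tail; read 1 lies in
unique genomic flank and anchors the insertion to a coordinate.

`teclust` provides the full computational pipeline over such libraries:

* **read-pair filtering** on primer match, TE-like sequence mismatches,
  poly-A corroboration, duplicates and mapping quality
  (`filter_pairs()`), with exclusive per-reason accounting;
* **positional clustering** of read-1 anchors into candidate insertion
  loci with support/span thresholds and genome-mask screening
  (`cluster_reads()`, `apply_cluster_thresholds()`, `apply_mask()`);
* **classification** of candidates as *reference*, *known
  non-reference* (polymorphic-TE database) or *novel* against annotation
  3' ends (`classify_clusters()`);
* **evaluation**: greedy one-to-one truth matching, precision/recall,
  trio inheritance (inherited vs de novo), long-read validation, and
  read-depth threshold sweeps (`run_evaluate()`, `sweep_read_depth()`);
* **primer-site genomics**: primer scanning with 3'-anchor rules,
  target/nested pairing, head-to-head inverted-repeat detection
  (`scan_primer()`, `build_target_set()`, `find_inverted_repeats()`);
* a **simulator** with planted ground truth that exercises every stage
  end to end (`simulate_genome_and_insertions()`, `simulate_library()`,
  `write_fixture()`).

See the vignette source in `vignettes/targeted-te-calling.Rmd` for the
method description.

## Worked example

Simulate a small genome with planted insertions, sequence it, call
insertions and evaluate against the planted truth:

```r
library(teclust)
profiles <- te_profiles()
cfg <- sim_config(seed = 7, genome_length_bp = 60000,
                  n_reference_insertions = 4, n_nonreference_insertions = 4,
                  fragments_per_locus = 6)
sim <- simulate_genome_and_insertions(profiles, cfg)
print(sim)
#> Simulated genome: 3 chromosome(s), 24 planted insertion(s) (12 reference, 12 non-reference)

pairs <- simulate_library(sim, profiles, "NA12878")
nrow(pairs)
#> [1] 210

res <- run_call(pairs, profiles = profiles,
                annotations = reference_annotations(sim, profiles))
res$calls[1:4, c("subfamily", "chrom", "start", "end",
                 "read1_count_hq", "status", "distance_bp")]
#>   subfamily chrom start   end read1_count_hq    status distance_bp
#> 1  AluYa5/8  chr2  9247  9493              6     novel          NA
#> 2  AluYa5/8  chr2 12357 12588              6 reference          21
#> 3  AluYa5/8  chr2 16345 16592              6 reference          32
#> 4  AluYa5/8  chr2 23697 23895              6 reference          31

table(res$calls$status)
#>     novel reference
#>        12        12

ev <- run_evaluate(res$calls[res$calls$status == "novel", ],
                   sim_truth(sim, "nonreference"), "mei")
print(ev$result)
#> TP 12  FP 0  FN 0  precision 1.0000  recall 1.0000

res$summaries[["L1HS"]]$reason_counts
#>                OK         DUPLICATE         NO_PRIMER    PARTIAL_PRIMER
#>                48                 0                21                 0
#> TE_LIKE_UNCOVERED  TE_LIKE_EXCEEDED    READ1_UNMAPPED         MAPQ_ZERO
#>                 0                 0                 0                 1
```

Every planted non-reference insertion is recovered as a novel call and
every reference planting is classified as reference; the 30% simulated
genomic background is removed by the primer filter (`NO_PRIMER`) and a
head-to-head artifact pair by the MAPQ-0 rule.

Real data enters through `read_alignments()` (one coordinate-sorted,
duplicate-marked SAM/BAM per sample-by-subfamily library) and flows
through the same `run_call()`; a thin command-line wrapper with
`simulate` / `call` / `evaluate` subcommands is installed at
`inst/scripts/teclust-cli.R`.

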