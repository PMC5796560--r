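p <- te_params()

mk_call <- function(start, end = start + 150L, chrom = "chr1",
                    subfamily = "L1HS", sample_id = "s1",
                    status = "novel") {
  data.frame(sample_id = sample_id, subfamily = subfamily, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             read1_count_hq = 3L, read1_total = 3L,
             read2_mapped_count = 0L, polya_count = 3L, status = status,
             stringsAsFactors = FALSE)
}

test_that("precision and recall handle defined and undefined cases", {
  r <- precision_recall(589, 9, 598 - 589)
  expect_equal(r$precision, 589 / 598, tolerance = 1e-12)
  expect_equal(r$recall, 589 / 598, tolerance = 1e-12)
  r <- precision_recall(5384, 0, 5692 - 5384)
  expect_equal(r$recall, 5384 / 5692, tolerance = 1e-12)
  expect_equal(round(r$recall, 2), 0.95)
  # no calls at all: precision undefined, recall 0
  r <- precision_recall(0, 0, 7)
  expect_false(r$precision_defined)
  expect_true(is.nan(r$precision))
  expect_equal(r$recall, 0)
  # empty truth: recall undefined
  r <- precision_recall(0, 3, 0)
  expect_false(r$recall_defined)
  expect_equal(r$precision, 0)
  expect_error(precision_recall(-1, 0, 0), "non-negative")
  expect_output(print(precision_recall(1, 1, 0)), "undefined|precision")
})

test_that("greedy matching is one-to-one within the anchor window", {
  truth <- truth_records(c("chr1", "chr1"), c(1075L, 5000L), "L1HS",
                         "LINE1", id = c("t1", "t2"))
  calls <- rbind(mk_call(1000L), mk_call(9000L))
  m <- match_calls_to_truth(calls, truth, p)
  expect_equal(m$tp$truth_id, "t1")
  expect_equal(m$tp$distance_bp, 0L)      # anchor inside the interval
  expect_equal(m$fp_calls, 2L)
  expect_equal(m$fn_truth, "t2")
  # one call cannot satisfy two nearby truth records
  truth2 <- truth_records("chr1", c(1075L, 1090L), "L1HS", "LINE1",
                          id = c("a", "b"))
  m <- match_calls_to_truth(mk_call(1000L), truth2, p)
  expect_equal(nrow(m$tp), 1L)
  expect_equal(m$tp$truth_id, "a")        # tie at 0 broken by truth id
  expect_equal(m$fn_truth, "b")
  # window boundary: 600 matches, 601 does not
  m <- match_calls_to_truth(mk_call(1000L),
                            truth_records("chr1", 1750L, "L1HS", "LINE1"), p)
  expect_equal(nrow(m$tp), 1L)
  m <- match_calls_to_truth(mk_call(1000L),
                            truth_records("chr1", 1751L, "L1HS", "LINE1"), p)
  expect_equal(nrow(m$tp), 0L)
  # subfamily-level matching separates the two Alu libraries,
  # class-level matching joins them
  tr <- truth_records("chr1", 1075L, "AluYb8", "Alu")
  m <- match_calls_to_truth(mk_call(1000L, subfamily = "AluYa5/8"), tr, p)
  expect_equal(nrow(m$tp), 0L)
  m <- match_calls_to_truth(mk_call(1000L, subfamily = "AluYa5/8"), tr, p,
                            match_level = "class")
  expect_equal(nrow(m$tp), 1L)
  m <- match_calls_to_truth(mk_call(1000L, subfamily = "AluYb8/9"), tr, p)
  expect_equal(nrow(m$tp), 1L)
})

test_that("matching equals the exhaustive brute-force matcher", {
  set.seed(71)
  for (trial in 1:20) {
    nt <- sample(1:100, 1); nc <- sample(1:40, 1)
    truth <- truth_records(rep("chr1", nt),
                           sample.int(30000L, nt, replace = TRUE),
                           "L1HS", "LINE1",
                           id = sprintf("t%03d", seq_len(nt)))
    calls <- do.call(rbind, lapply(
      sample.int(30000L, nc, replace = TRUE), mk_call))
    got <- match_calls_to_truth(calls, truth, p)
    want <- bf_match(calls, truth, p$annotation_window_bp)
    expect_setequal(
      paste(got$tp$call_idx, got$tp$truth_id, got$tp$distance_bp),
      paste(want$tp$call_idx, want$tp$truth_id, want$tp$distance_bp))
    expect_setequal(got$fp_calls, want$fp_calls)
    expect_setequal(got$fn_truth, want$fn_truth)
    # conservation: every call is TP or FP, every truth TP or FN
    expect_equal(nrow(got$tp) + length(got$fp_calls), nc)
    expect_equal(nrow(got$tp) + length(got$fn_truth), nt)
  }
})

test_that("parental truth keeps only sites detected in both parents", {
  p1 <- rbind(mk_call(1000L), mk_call(5000L), mk_call(9000L))
  p2 <- rbind(mk_call(1030L), mk_call(5300L))   # 5300 is 150 bp beyond p1's end
  tr <- build_parental_truth(p1, p2, p)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$source, "parental_truth")
  # anchor is the midpoint of the two interval midpoints
  expect_equal(tr$anchor, as.integer(round(((1000 + 1150) / 2 +
                                              (1030 + 1180) / 2) / 2)))
  # edge distance 150 bp exceeds the 100 bp parental window
  expect_equal(.interval_distance(5000L, 5150L, 5300L, 5450L), 150L)
  # subfamilies never cross-match
  q2 <- transform(p2[1, ], subfamily = "AluYa5/8")
  expect_equal(nrow(build_parental_truth(p1, q2, p)), 0L)
  # empty parents give an empty truth set
  expect_equal(nrow(build_parental_truth(p1[0, ], p2, p)), 0L)
})

test_that("proband novel calls split by single-read parental evidence", {
  calls <- rbind(mk_call(1000L), mk_call(8000L))
  # parent 1 has one kept read near the first call only
  par1 <- make_kept_pairs(1100L)
  par2 <- make_kept_pairs(integer(0))
  sp <- classify_proband_novel(calls, par1, par2, p)
  expect_equal(sp$inherited$start, 1000L)
  expect_equal(sp$de_novo$start, 8000L)
  # evidence in either parent suffices
  sp <- classify_proband_novel(calls, par2, par1, p)
  expect_equal(nrow(sp$de_novo), 1L)
  # a dropped (non-keep) read is not evidence
  bad <- par1; bad$verdict <- "drop"
  sp <- classify_proband_novel(calls, bad, par2, p)
  expect_equal(nrow(sp$de_novo), 2L)
  # read 101 bp from the call edge is outside the parental window
  far <- make_kept_pairs(1000L + 150L + 101L)
  sp <- classify_proband_novel(calls[1, ], far, par2, p)
  expect_equal(nrow(sp$de_novo), 1L)
  near <- make_kept_pairs(1000L + 150L + 100L)
  sp <- classify_proband_novel(calls[1, ], near, par2, p)
  expect_equal(nrow(sp$inherited), 1L)
})

test_that("long-read validation needs full span plus the TE-like sequence", {
  prof <- te_profiles()$L1HS
  call <- mk_call(1000L)
  ctx <- function(mid) paste0(random_dna(40), mid, random_dna(40))
  set.seed(72)
  lr <- data.frame(
    chrom = "chr1",
    start = c(900L, 900L, 1050L, 900L),
    end = c(1300L, 1300L, 1300L, 1300L),
    seq = c(ctx(prof$te_like),                 # spans + TE-like: support
            ctx("TTTTTTTT"),                   # spans, no TE-like
            ctx(prof$te_like),                 # TE-like but no full span
            ctx(as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(prof$te_like))))),  # reverse orientation
    stringsAsFactors = FALSE)
  expect_equal(validate_with_long_reads(call, lr, prof), 2L)
  expect_equal(validate_with_long_reads(call, lr[0, ], prof), 0L)
  expect_equal(validate_with_long_reads(call, NULL, prof), 0L)
})

test_that("support summary and mismatch density are computed per position", {
  calls <- rbind(mk_call(1000L), mk_call(5000L),
                 mk_call(9000L, subfamily = "AluYa5/8"))
  calls$polya_count <- c(2L, 3L, 1L)
  s <- summarize_support(calls)
  expect_equal(s$polya_ratio[s$subfamily == "L1HS"], 5 / 6)
  expect_equal(s$polya_ratio[s$subfamily == "AluYa5/8"], 1 / 3)
  expect_equal(nrow(summarize_support(calls[0, ])), 0L)
  prof <- te_profiles()$`AluYa5/8`
  mut <- prof$te_like
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(mut, 3, 3))[1]
  reads <- paste0(prof$nested_primer, c(prof$te_like, mut))
  d <- mismatch_density(reads, prof)
  expect_equal(length(d), 37L)
  expect_equal(d[3], 0.5)
  expect_true(all(d[-3] == 0))
  # positions nobody covers are NaN
  d <- mismatch_density(paste0(prof$nested_primer,
                               substr(prof$te_like, 1, 5)), prof)
  expect_true(all(is.nan(d[6:37])))
})
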