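pf <- te_profiles()
p <- te_params()

test_that("primer classification distinguishes full, partial and background", {
  np <- pf$L1HS$nested_primer
  set.seed(31)
  tail <- random_dna(120)
  expect_equal(classify_primer_match(paste0(np, tail), np, p), "FULL")
  # 7 of the first 10 bases match, but not the full primer
  pre <- np
  for (j in c(2, 5, 9))
    substr(pre, j, j) <- setdiff(c("A","C","G","T"), substr(pre, j, j))[1]
  expect_equal(classify_primer_match(paste0(pre, tail), np, p), "PARTIAL")
  # 5 of 10: background
  for (j in c(3, 7))
    substr(pre, j, j) <- setdiff(c("A","C","G","T"), substr(pre, j, j))[1]
  expect_equal(classify_primer_match(paste0(pre, tail), np, p), "NONE")
  # 6 of 10 stays background at the default 7/10 rule, passes at 6/10
  pre6 <- np
  for (j in c(2, 4, 6, 8))
    substr(pre6, j, j) <- setdiff(c("A","C","G","T"), substr(pre6, j, j))[1]
  expect_equal(classify_primer_match(paste0(pre6, tail), np, p), "NONE")
  expect_equal(classify_primer_match(
    paste0(pre6, tail), np, te_params(primer_partial_min_matches = 6)),
    "PARTIAL")
  expect_error(classify_primer_match("", np, p), "non-empty")
})

test_that("TE-like mismatches are counted over covered positions only", {
  prof <- pf$`AluYa5/8`
  np <- prof$nested_primer
  r <- paste0(np, prof$te_like, strrep("A", 20))
  expect_equal(te_like_mismatches(r, prof),
               list(mismatches = 0L, covered = 37L))
  mut <- prof$te_like
  substr(mut, 10, 10) <- setdiff(c("A","C","G","T"), substr(mut, 10, 10))[1]
  expect_equal(te_like_mismatches(paste0(np, mut), prof)$mismatches, 1L)
  # truncated read covers only part of the TE-like region
  short <- paste0(np, substr(prof$te_like, 1, 12))
  expect_equal(te_like_mismatches(short, prof),
               list(mismatches = 0L, covered = 12L))
  expect_equal(te_like_mismatches(np, prof)$covered, 0L)
})

test_that("poly-A detection scans windows downstream of the TE-like region", {
  prof <- pf$L1HS
  base <- paste0(prof$nested_primer, prof$te_like)
  expect_true(detect_polya(paste0(base, strrep("A", 20)), prof, p))
  expect_false(detect_polya(paste0(base, strrep("A", 7)), prof, p))
  expect_false(detect_polya(paste0(prof$nested_primer,
                                   substr(prof$te_like, 1, 4)), prof, p))
  # one non-A inside the run is tolerated, two are not
  expect_true(detect_polya(paste0(base, "AAAGAAAA"), prof, p))
  expect_false(detect_polya(paste0(base, "AAGAAGAA"), prof, p))
})

test_that("pair filtering applies rules in order and never requires read 2", {
  prof <- pf$L1HS
  good <- paste0(prof$nested_primer, prof$te_like, strrep("A", 20),
                 "CGTACGTACG")
  as_pair <- function(row) list(
    read1 = list(chrom = row$chrom, start = row$start, end = row$end,
                 strand = row$strand, mapq = row$mapq,
                 is_mapped = row$r1_mapped),
    read2 = list(sequence = row$r2_seq, is_mapped = row$r2_mapped,
                 mapq = row$r2_mapq),
    is_duplicate = row$is_duplicate)
  r <- filter_pair(as_pair(make_pair(good)), prof, p)
  expect_equal(r$verdict, "keep")
  expect_equal(r$reason, "OK")
  expect_true(r$polya_detected)
  # read 2 unmapped is irrelevant when read 1 maps well
  r <- filter_pair(as_pair(make_pair(good, mapq = 10, r2_mapped = FALSE)),
                   prof, p)
  expect_equal(r$verdict, "keep")
  # MAPQ 0 on read 1 removes the pair after primer/TE-like checks
  r <- filter_pair(as_pair(make_pair(good, mapq = 0)), prof, p)
  expect_equal(r$reason, "MAPQ_ZERO")
  r <- filter_pair(as_pair(make_pair(good, r1_mapped = FALSE)), prof, p)
  expect_equal(r$reason, "READ1_UNMAPPED")
  r <- filter_pair(as_pair(make_pair(good, is_duplicate = TRUE)), prof, p)
  expect_equal(r$reason, "DUPLICATE")
  # L1HS cap is 3: four TE-like mismatches drop the pair
  mut <- prof$te_like
  for (j in 1:4)
    substr(mut, j, j) <- setdiff(c("A","C","G","T"), substr(mut, j, j))[1]
  r <- filter_pair(as_pair(make_pair(paste0(prof$nested_primer, mut))),
                   prof, p)
  expect_equal(r$reason, "TE_LIKE_EXCEEDED")
  # AluYa5/8 cap is 10: 11 mismatches drop, 10 keep
  prof2 <- pf$`AluYa5/8`
  mut2 <- prof2$te_like
  for (j in 1:11)
    substr(mut2, j, j) <- setdiff(c("A","C","G","T"), substr(mut2, j, j))[1]
  r <- filter_pair(as_pair(make_pair(paste0(prof2$nested_primer, mut2))),
                   prof2, p)
  expect_equal(r$reason, "TE_LIKE_EXCEEDED")
  mut10 <- prof2$te_like
  for (j in 1:10)
    substr(mut10, j, j) <- setdiff(c("A","C","G","T"), substr(mut10, j, j))[1]
  r <- filter_pair(as_pair(make_pair(paste0(prof2$nested_primer, mut10))),
                   prof2, p)
  expect_equal(r$verdict, "keep")
  # read ending exactly at the primer covers no TE-like base
  r <- filter_pair(as_pair(make_pair(prof$nested_primer)), prof, p)
  expect_equal(r$reason, "TE_LIKE_UNCOVERED")
  expect_error(filter_pair(list(read1 = list(), read2 = list(sequence = NA),
                                is_duplicate = FALSE), prof, p), "missing")
  # purity: identical input gives identical result
  pr <- make_pair(good)
  expect_identical(filter_pair(as_pair(pr), prof, p),
                   filter_pair(as_pair(pr), prof, p))
})

test_that("raising the mismatch cap never shrinks the kept set", {
  set.seed(32)
  prof <- pf$`AluYb8/9`
  reads <- vapply(1:60, function(i) {
    tl <- strsplit(prof$te_like, "")[[1]]
    k <- sample(0:15, 1)
    for (j in sample(seq_along(tl), k))
      tl[j] <- sample(setdiff(c("A","C","G","T"), tl[j]), 1)
    paste0(prof$nested_primer, paste(tl, collapse = ""), strrep("A", 12))
  }, character(1))
  tab <- do.call(rbind, lapply(seq_along(reads), function(i)
    make_pair(reads[i], id = paste0("p", i), subfamily = "AluYb8/9")))
  kept_at <- function(cap) {
    prof2 <- prof; prof2$max_te_like_mismatches <- cap
    f <- filter_pairs(tab, prof2, p)
    f$id[f$verdict == "keep"]
  }
  prev <- character(0)
  for (cap in c(0, 3, 6, 10, 15)) {
    cur <- kept_at(cap)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # lowering the partial threshold never loses FULL+PARTIAL classifications
  disc_at <- function(minm) {
    f <- filter_pairs(tab, prof,
                      te_params(primer_partial_min_matches = minm))
    f$id[f$primer_class %in% c("FULL", "PARTIAL")]
  }
  expect_true(all(disc_at(9) %in% disc_at(7)))
  expect_true(all(disc_at(7) %in% disc_at(5)))
})

test_that("filter summary conserves pair counts and reports fractions", {
  sim <- small_sim()
  pairs <- simulate_library(sim, pf, "sF", seed = 33)
  for (sf in names(pf)) {
    tab <- pairs[pairs$subfamily == sf, ]
    f <- filter_pairs(tab, pf[[sf]], p)
    s <- filter_summary(f)
    expect_equal(sum(s$reason_counts), nrow(tab))
    expect_equal(s$n_pairs, nrow(tab))
    expect_true(s$primer_full_fraction <= s$primer_discernible_fraction)
    # error-free on-target reads all carry a poly-A tail
    expect_equal(s$polya_fraction_kept, 1)
  }
})

test_that("background fraction is recovered by the NO_PRIMER drop rate", {
  sim <- small_sim()
  cfg <- sim$config
  pairs <- simulate_library(sim, pf, "sB", seed = 34)
  f <- do.call(rbind, lapply(names(pf), function(sf)
    filter_pairs(pairs[pairs$subfamily == sf, ], pf[[sf]], p)))
  frac <- mean(f$reason == "NO_PRIMER")
  # binomial tolerance around the configured background fraction
  n <- nrow(f)
  tol <- 4 * sqrt(cfg$background_fraction * (1 - cfg$background_fraction) / n) +
    0.01
  expect_lt(abs(frac - cfg$background_fraction), tol)
})
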