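#' Classify the nested-primer match at the start of read 2
#'
#' Read 2 of an on-target pair begins with the nested primer. `FULL`
#' requires the complete primer as an exact prefix of the read; `PARTIAL`
#' (a discernible but imperfect match) requires at least
#' `primer_partial_min_matches` position-wise matches within the first
#' `primer_prefix_len` primer bases; anything weaker is `NONE` (genomic
#' background). Only `FULL` pairs are retained by [filter_pair()];
#' `PARTIAL` is tallied separately because it separates background from
#' discernible reads in the on-target report.
#'
#' @param read2_sequence read 2 sequence (as sequenced, 5' to 3').
#' @param nested_primer the library's nested primer.
#' @param params a [te_params()] object.
#' @return One of `"FULL"`, `"PARTIAL"`, `"NONE"`.
#' @export
classify_primer_match <- function(read2_sequence, nested_primer,
                                  params = te_params()) {
  if (!nzchar(read2_sequence)) stop("read 2 sequence must be non-empty")
  np <- nchar(nested_primer)
  if (nchar(read2_sequence) >= np &&
      substr(read2_sequence, 1L, np) == nested_primer)
    return("FULL")
  k <- min(params$primer_prefix_len, np, nchar(read2_sequence))
  if (k > 0L) {
    a <- strsplit(substr(read2_sequence, 1L, k), "")[[1]]
    b <- strsplit(substr(nested_primer, 1L, k), "")[[1]]
    if (sum(a == b) >= params$primer_partial_min_matches)
      return("PARTIAL")
  }
  "NONE"
}

#' Count mismatches to the TE-like sequence
#'
#' Compares the read bases immediately following the nested primer,
#' position-wise, against the profile's TE-like sequence (substitutions
#' only; the exact primer anchor fixes the frame, so no indel alignment is
#' attempted). Only positions the read actually covers are compared.
#'
#' @param read2_sequence read 2 sequence; the caller must have established
#'   a `FULL` primer match.
#' @param profile a [te_profile()] object.
#' @return List with `mismatches` (integer, `NA` when `covered` is 0) and
#'   `covered` (number of TE-like positions covered by the read).
#' @export
te_like_mismatches <- function(read2_sequence, profile) {
  np <- nchar(profile$nested_primer)
  tl <- profile$te_like
  tail <- substr(read2_sequence, np + 1L, np + nchar(tl))
  covered <- nchar(tail)
  if (covered == 0L)
    return(list(mismatches = NA_integer_, covered = 0L))
  a <- strsplit(tail, "")[[1]]
  b <- strsplit(substr(tl, 1L, covered), "")[[1]]
  list(mismatches = sum(a != b), covered = covered)
}

#' Detect a poly-A tail downstream of the TE-like region
#'
#' Retrotransposition appends a poly-A tail, so its presence corroborates
#' a true insertion. Scans the read 3' of the TE-like region for any
#' window of `polya_min_run` bases containing at most `polya_max_nonA`
#' non-A bases. Annotation only: the result never changes a filter
#' verdict.
#'
#' @inheritParams te_like_mismatches
#' @param params a [te_params()] object.
#' @return `TRUE` or `FALSE`.
#' @export
detect_polya <- function(read2_sequence, profile, params = te_params()) {
  offset <- nchar(profile$nested_primer) + nchar(profile$te_like)
  region <- substr(read2_sequence, offset + 1L, nchar(read2_sequence))
  w <- params$polya_min_run
  n <- nchar(region)
  if (n < w) return(FALSE)
  nonA <- as.integer(strsplit(region, "")[[1]] != "A")
  cs <- c(0L, cumsum(nonA))
  any(cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)] <= params$polya_max_nonA)
}

#' Filter one aligned read pair
#'
#' Applies the mobilome/background discrimination rules in order:
#' duplicate flag; nested-primer classification (only `FULL` survives);
#' TE-like mismatch cap; read-1 mapping state; read-1 mapping quality
#' (MAPQ below `min_report_mapq`, i.e. MAPQ 0 by default, is removed).
#' Read 2 mapping state is never required: non-reference insertions
#' routinely leave read 2 unmapped or multi-mapping while read 1, from the
#' unique flank, anchors the locus.
#'
#' @param pair a list with elements `read1` (list: `chrom`, `start`,
#'   `end`, `strand`, `mapq`, `is_mapped`), `read2` (list: `sequence`,
#'   `is_mapped`, `mapq`) and `is_duplicate`.
#' @param profile a [te_profile()] object.
#' @param params a [te_params()] object.
#' @return A list of class `"filter_result"`: `verdict` (`"keep"` or
#'   `"drop"`), `reason` (one of `OK`, `DUPLICATE`, `NO_PRIMER`,
#'   `PARTIAL_PRIMER`, `TE_LIKE_UNCOVERED`, `TE_LIKE_EXCEEDED`,
#'   `READ1_UNMAPPED`, `MAPQ_ZERO`), `primer_class`,
#'   `te_like_mismatches`, `te_like_covered`, `polya_detected`.
#' @export
filter_pair <- function(pair, profile, params = te_params()) {
  r2 <- pair$read2$sequence
  if (is.null(r2) || is.na(r2) || !nzchar(r2))
    stop("read 2 sequence is missing")
  pc <- classify_primer_match(r2, profile$nested_primer, params)
  mis <- NA_integer_; cov <- 0L; polya <- FALSE
  if (pc == "FULL") {
    tl <- te_like_mismatches(r2, profile)
    mis <- tl$mismatches; cov <- tl$covered
    polya <- detect_polya(r2, profile, params)
  }
  reason <-
    if (isTRUE(pair$is_duplicate)) "DUPLICATE"
    else if (pc == "NONE") "NO_PRIMER"
    else if (pc == "PARTIAL") "PARTIAL_PRIMER"
    else if (cov == 0L) "TE_LIKE_UNCOVERED"
    else if (mis > profile$max_te_like_mismatches) "TE_LIKE_EXCEEDED"
    else if (!isTRUE(pair$read1$is_mapped)) "READ1_UNMAPPED"
    else if (pair$read1$mapq < params$min_report_mapq) "MAPQ_ZERO"
    else "OK"
  structure(list(
    verdict = if (reason == "OK") "keep" else "drop",
    reason = reason, primer_class = pc,
    te_like_mismatches = mis, te_like_covered = cov,
    polya_detected = polya), class = "filter_result")
}

#' Filter a table of read pairs
#'
#' Vectorised driver over [filter_pair()] for a whole library.
#'
#' @param pairs data frame with one row per pair and columns `chrom`,
#'   `start`, `end`, `strand`, `mapq`, `r1_mapped`, `r2_seq`,
#'   `is_duplicate` (as produced by [read_alignments()] or
#'   [simulate_library()]).
#' @inheritParams filter_pair
#' @return The input with appended columns `verdict`, `reason`,
#'   `primer_class`, `te_like_mismatches`, `te_like_covered`,
#'   `polya_detected`.
#' @export
filter_pairs <- function(pairs, profile, params = te_params()) {
  n <- nrow(pairs)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- filter_pair(list(
      read1 = list(chrom = pairs$chrom[i], start = pairs$start[i],
                   end = pairs$end[i], strand = pairs$strand[i],
                   mapq = pairs$mapq[i], is_mapped = pairs$r1_mapped[i]),
      read2 = list(sequence = pairs$r2_seq[i],
                   is_mapped = pairs$r2_mapped[i],
                   mapq = pairs$r2_mapq[i]),
      is_duplicate = pairs$is_duplicate[i]), profile, params)
  }
  pairs$verdict <- vapply(res, `[[`, character(1), "verdict")
  pairs$reason <- vapply(res, `[[`, character(1), "reason")
  pairs$primer_class <- vapply(res, `[[`, character(1), "primer_class")
  pairs$te_like_mismatches <- vapply(res, `[[`, integer(1), "te_like_mismatches")
  pairs$te_like_covered <- vapply(res, `[[`, integer(1), "te_like_covered")
  pairs$polya_detected <- vapply(res, `[[`, logical(1), "polya_detected")
  pairs
}

#' Per-library filter summary
#'
#' Tallies filter outcomes for a library: counts by drop reason, the
#' fraction of pairs with a discernible (full or partial) primer match,
#' and the poly-A fraction among kept pairs. Both the strict (full-only)
#' and permissive (full+partial) on-target fractions are reported.
#'
#' @param filtered output of [filter_pairs()].
#' @return A list with `reason_counts` (named integer vector over all
#'   reasons), `n_pairs`, `primer_full_fraction`,
#'   `primer_discernible_fraction`, `polya_fraction_kept`.
#' @export
filter_summary <- function(filtered) {
  reasons <- c("OK", "DUPLICATE", "NO_PRIMER", "PARTIAL_PRIMER",
               "TE_LIKE_UNCOVERED", "TE_LIKE_EXCEEDED", "READ1_UNMAPPED",
               "MAPQ_ZERO")
  counts <- setNames(integer(length(reasons)), reasons)
  tab <- table(filtered$reason)
  counts[names(tab)] <- as.integer(tab)
  n <- nrow(filtered)
  kept <- filtered$verdict == "keep"
  list(
    reason_counts = counts,
    n_pairs = n,
    primer_full_fraction =
      if (n) mean(filtered$primer_class == "FULL") else NA_real_,
    primer_discernible_fraction =
      if (n) mean(filtered$primer_class %in% c("FULL", "PARTIAL")) else NA_real_,
    polya_fraction_kept =
      if (any(kept)) mean(filtered$polya_detected[kept]) else NA_real_)
}
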