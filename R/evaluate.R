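#' Construct a truth record table
#'
#' @param chrom chromosome names.
#' @param anchor 3' terminal positions (1-based) of the true insertions.
#' @param subfamily subfamily names; may be `NA` for class-only records
#'   (e.g. MEI call sets lacking subfamily designations).
#' @param te_class `"LINE1"` or `"Alu"`.
#' @param source one of `"reference_truth"`, `"mei_truth"`,
#'   `"parental_truth"`.
#' @param id unique identifiers; generated when missing.
#' @return Data frame of truth records.
#' @export
truth_records <- function(chrom, anchor, subfamily = NA_character_,
                          te_class, source = "reference_truth", id = NULL) {
  n <- length(chrom)
  data.frame(chrom = chrom, anchor = as.integer(anchor),
             subfamily = rep_len(subfamily, n),
             te_class = rep_len(te_class, n),
             source = rep_len(source, n),
             id = if (is.null(id)) sprintf("truth%05d", seq_len(n)) else id,
             stringsAsFactors = FALSE)
}

.library_class <- function(subfamily) {
  map <- c("L1HS" = "LINE1", "AluYa5/8" = "Alu", "AluYb8/9" = "Alu")
  ifelse(subfamily %in% names(map), map[subfamily], subfamily)
}

#' Match calls against a truth set
#'
#' A truth record is a true positive when a call of the required level
#' (subfamily match for reference truth, class match for MEI truth whose
#' subfamily designations are incomplete) lies within
#' `annotation_window_bp` of its 3' anchor. Matching is greedy and
#' one-to-one by increasing distance, so one call cannot satisfy two
#' truth records. Unmatched truth records are false negatives; unmatched
#' calls are false positives.
#'
#' @param calls call/cluster table with `chrom`, `start`, `end`,
#'   `subfamily`.
#' @param truth truth table from [truth_records()].
#' @param params a [te_params()] object.
#' @param match_level `"subfamily"` or `"class"`.
#' @param synonyms subfamily synonym groups for subfamily-level matching.
#' @return List with `tp` (data frame: `call_idx`, `truth_id`,
#'   `distance_bp`), `fp_calls` (row indices into `calls`), `fn_truth`
#'   (truth ids).
#' @export
match_calls_to_truth <- function(calls, truth, params = te_params(),
                                 match_level = c("subfamily", "class"),
                                 synonyms = subfamily_synonyms()) {
  match_level <- match.arg(match_level)
  nc <- nrow(calls); nt <- nrow(truth)
  cand <- list()
  if (nc && nt) {
    call_class <- .library_class(calls$subfamily)
    for (i in seq_len(nc)) {
      if (match_level == "subfamily") {
        syn <- if (calls$subfamily[i] %in% names(synonyms))
          synonyms[[calls$subfamily[i]]] else calls$subfamily[i]
        lev <- truth$subfamily %in% syn | truth$subfamily %in% calls$subfamily[i]
      } else {
        lev <- truth$te_class == call_class[i]
      }
      sel <- which(truth$chrom == calls$chrom[i] & lev)
      if (!length(sel)) next
      d <- .anchor_distance(calls$start[i], calls$end[i], truth$anchor[sel])
      ok <- d <= params$annotation_window_bp
      if (any(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          call_idx = i, truth_id = truth$id[sel[ok]],
          distance_bp = as.integer(d[ok]), stringsAsFactors = FALSE)
    }
  }
  tp <- data.frame(call_idx = integer(), truth_id = character(),
                   distance_bp = integer())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$distance_bp, cand$truth_id, cand$call_idx), ,
                 drop = FALSE]
    used_call <- logical(nc)
    used_truth <- character(0)
    for (k in seq_len(nrow(cand))) {
      ci <- cand$call_idx[k]; ti <- cand$truth_id[k]
      if (used_call[ci] || ti %in% used_truth) next
      used_call[ci] <- TRUE
      used_truth <- c(used_truth, ti)
      tp <- rbind(tp, cand[k, , drop = FALSE])
    }
  }
  rownames(tp) <- NULL
  list(tp = tp,
       fp_calls = setdiff(seq_len(nc), tp$call_idx),
       fn_truth = setdiff(truth$id, tp$truth_id))
}

#' Precision and recall from TP/FP/FN counts
#'
#' Recall = TP/(TP+FN); precision = TP/(TP+FP). A metric whose
#' denominator is zero is reported as `NaN` with its `*_defined` flag set
#' to `FALSE`.
#'
#' @param tp,fp,fn non-negative counts.
#' @return List of class `"eval_result"` with elements `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `precision_defined`, `recall_defined`.
#' @examples
#' precision_recall(589, 9, 35)
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
    recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
    precision_defined = tp + fp > 0,
    recall_defined = tp + fn > 0), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  precision %s  recall %s\n",
              x$tp, x$fp, x$fn,
              if (x$precision_defined) sprintf("%.4f", x$precision) else "undefined",
              if (x$recall_defined) sprintf("%.4f", x$recall) else "undefined"))
  invisible(x)
}

#' Build a parental truth set from two parents' clusters
#'
#' The parental truth set of a trio consists of insertions detected at
#' the same location, to within `parental_window_bp`, in both parents.
#' Cluster pairs are matched greedily one-to-one by edge distance
#' (overlap counts as 0) within the same subfamily; each matched pair
#' yields one truth record anchored at the midpoint of the two intervals.
#'
#' @param parent1_clusters,parent2_clusters cluster tables processed with
#'   identical parameters.
#' @param params a [te_params()] object.
#' @return Truth table as from [truth_records()] with
#'   `source = "parental_truth"`.
#' @export
build_parental_truth <- function(parent1_clusters, parent2_clusters,
                                 params = te_params()) {
  empty <- truth_records(character(0), integer(0), character(0),
                         character(0), "parental_truth", character(0))
  n1 <- nrow(parent1_clusters); n2 <- nrow(parent2_clusters)
  if (!n1 || !n2) return(empty)
  cand <- list()
  for (i in seq_len(n1)) {
    sel <- which(parent2_clusters$chrom == parent1_clusters$chrom[i] &
                   parent2_clusters$subfamily == parent1_clusters$subfamily[i])
    if (!length(sel)) next
    d <- .interval_distance(parent1_clusters$start[i], parent1_clusters$end[i],
                            parent2_clusters$start[sel],
                            parent2_clusters$end[sel])
    ok <- d <= params$parental_window_bp
    if (any(ok))
      cand[[length(cand) + 1L]] <- data.frame(i = i, j = sel[ok],
                                              d = d[ok])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
  used1 <- logical(n1); used2 <- logical(n2)
  rec <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    mid1 <- (parent1_clusters$start[i] + parent1_clusters$end[i]) / 2
    mid2 <- (parent2_clusters$start[j] + parent2_clusters$end[j]) / 2
    rec[[length(rec) + 1L]] <- data.frame(
      chrom = parent1_clusters$chrom[i],
      anchor = as.integer(round((mid1 + mid2) / 2)),
      subfamily = parent1_clusters$subfamily[i], stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rec)
  truth_records(rec$chrom, rec$anchor, rec$subfamily,
                .library_class(rec$subfamily), "parental_truth")
}

# edge distance between two intervals (0 when they overlap)
.interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Split a proband's novel calls into inherited and de novo
#'
#' Because virtually every insertion in a genome is observed with at
#' least one read, de novo status in the proband is defined
#' conservatively: a novel call is inherited if either parent has at
#' least one filtered read-1 within `parental_window_bp` of the call
#' (threshold requirements bypassed); only calls lacking even one read in
#' both parents are de novo, and those count as false positives for
#' precision.
#'
#' @param proband_novel_calls call table of the proband's novel calls.
#' @param parent1_pairs,parent2_pairs filtered (kept) read-pair tables of
#'   the parents at the relaxed single-read level.
#' @param params a [te_params()] object.
#' @return List with `inherited` and `de_novo` call tables.
#' @export
classify_proband_novel <- function(proband_novel_calls, parent1_pairs,
                                   parent2_pairs, params = te_params()) {
  n <- nrow(proband_novel_calls)
  inherited <- logical(n)
  for (i in seq_len(n)) {
    ev <- FALSE
    for (pp in list(parent1_pairs, parent2_pairs)) {
      if (is.null(pp) || nrow(pp) == 0L) next
      if (!is.null(pp$verdict)) pp <- pp[pp$verdict == "keep", , drop = FALSE]
      sel <- pp$chrom == proband_novel_calls$chrom[i] &
        pp$subfamily == proband_novel_calls$subfamily[i]
      if (!any(sel)) next
      d <- .interval_distance(proband_novel_calls$start[i],
                              proband_novel_calls$end[i],
                              pp$start[sel], pp$end[sel])
      if (any(d <= params$parental_window_bp)) { ev <- TRUE; break }
    }
    inherited[i] <- ev
  }
  list(inherited = proband_novel_calls[inherited, , drop = FALSE],
       de_novo = proband_novel_calls[!inherited, , drop = FALSE])
}

#' Validate a call with long-read alignments
#'
#' Counts long reads whose alignment footprint fully spans the call's
#' cluster interval and whose sequence contains the subfamily's TE-like
#' sequence as an exact substring in either orientation. A call is
#' validated when at least one such read exists.
#'
#' @param call one call (single-row data frame with `chrom`, `start`,
#'   `end`).
#' @param long_reads data frame with `chrom`, `start`, `end` (alignment
#'   footprint) and `seq` (read sequence), e.g. from
#'   [read_long_reads()].
#' @param profile a [te_profile()] supplying the TE-like sequence.
#' @return Integer support count.
#' @export
validate_with_long_reads <- function(call, long_reads, profile) {
  if (is.null(long_reads) || nrow(long_reads) == 0L) return(0L)
  span <- long_reads$chrom == call$chrom &
    long_reads$start <= call$start & long_reads$end >= call$end
  if (!any(span)) return(0L)
  tl <- profile$te_like
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tl)))
  seqs <- long_reads$seq[span]
  sum(grepl(tl, seqs, fixed = TRUE) | grepl(rc, seqs, fixed = TRUE))
}

#' Per-subfamily read-support summary
#'
#' Totals, per subfamily, the reads spanning reported calls and how many
#' of them carry a poly-A corroboration, with their ratio.
#'
#' @param calls classified call table carrying `read1_total` and
#'   `polya_count`.
#' @return Data frame with `subfamily`, `total_reads`, `polya_reads`,
#'   `polya_ratio`; empty when there are no calls.
#' @export
summarize_support <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(subfamily = character(), total_reads = integer(),
                      polya_reads = integer(), polya_ratio = numeric()))
  agg <- aggregate(cbind(total_reads = read1_total,
                         polya_reads = polya_count) ~ subfamily,
                   data = calls, FUN = sum)
  agg$polya_ratio <- agg$polya_reads / agg$total_reads
  agg
}

#' Per-position TE-like mismatch density
#'
#' For a set of read-2 sequences with full primer matches, returns the
#' fraction of reads mismatching the TE-like sequence at each TE-like
#' position (covered positions only). Used descriptively to contrast
#' read populations, e.g. reads under true-positive versus
#' false-positive calls.
#'
#' @param read2_sequences character vector of read-2 sequences.
#' @param profile a [te_profile()] object.
#' @return Numeric vector of length `nchar(profile$te_like)`; `NaN` at
#'   positions no read covers.
#' @export
mismatch_density <- function(read2_sequences, profile) {
  np <- nchar(profile$nested_primer)
  tl <- strsplit(profile$te_like, "")[[1]]
  L <- length(tl)
  mism <- cov <- numeric(L)
  for (s in read2_sequences) {
    tail <- substr(s, np + 1L, np + L)
    k <- nchar(tail)
    if (k == 0L) next
    a <- strsplit(tail, "")[[1]]
    mism[1:k] <- mism[1:k] + (a != tl[1:k])
    cov[1:k] <- cov[1:k] + 1
  }
  mism / cov
}

#' Precision/recall sweep over the cluster read-depth threshold
#'
#' Recomputes precision and recall against a truth set while sweeping the
#' minimum high-quality read-1 support per cluster, holding all other
#' thresholds fixed. Raising the threshold can only drop calls, so recall
#' is non-increasing; spurious low-support clusters disappear first, so
#' precision is non-decreasing on data with planted truth.
#'
#' @param clusters cluster table (post-mask, pre-threshold).
#' @param truth truth table from [truth_records()].
#' @param params a [te_params()] object.
#' @param thresholds integer vector of support thresholds to sweep.
#' @param match_level `"subfamily"` or `"class"`.
#' @return Data frame with one row per threshold: `threshold`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`.
#' @export
sweep_read_depth <- function(clusters, truth, params = te_params(),
                             thresholds = 1:10,
                             match_level = "subfamily") {
  out <- lapply(thresholds, function(k) {
    p <- params
    p$min_read1_per_cluster <- as.integer(k)
    calls <- apply_cluster_thresholds(clusters, p)
    m <- match_calls_to_truth(calls, truth, params, match_level)
    pr <- precision_recall(nrow(m$tp), length(m$fp_calls), length(m$fn_truth))
    data.frame(threshold = k, tp = pr$tp, fp = pr$fp, fn = pr$fn,
               precision = pr$precision, recall = pr$recall)
  })
  do.call(rbind, out)
}
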