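# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle is deliberately naive so it shares no code path
# with the implementation it checks.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force transitive-closure clustering of 1-D start positions:
# two reads are linked when their starts are within `gap`; clusters are
# the connected components, computed by iterated label propagation
bf_cluster_ids <- function(starts, gap) {
  n <- length(starts)
  if (n == 0L) return(integer(0))
  lab <- seq_len(n)
  adj <- abs(outer(starts, starts, "-")) <= gap
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(lab[adj[i, ]])
      if (m < lab[i]) { lab[i] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  match(lab, unique(lab[order(starts)]))
}

# brute-force Hamming primer scan over both strands
bf_scan <- function(seq_chr, primer, max_mm) {
  revcomp_chr <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  np <- nchar(primer)
  pc <- strsplit(primer, "")[[1]]
  rows <- list()
  for (st in seq_len(nchar(seq_chr) - np + 1L)) {
    win <- substr(seq_chr, st, st + np - 1L)
    wc <- strsplit(win, "")[[1]]
    if (any(wc == "N")) next
    # forward
    mm <- sum(wc != pc)
    if (mm <= max_mm && wc[np] == pc[np])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "seq", start = st, end = st + np - 1L, strand = "+",
        n_mismatch = mm, stringsAsFactors = FALSE)
    # reverse: the primer read 5'->3' along the minus strand
    rc <- strsplit(revcomp_chr(win), "")[[1]]
    mm <- sum(rc != pc)
    if (mm <= max_mm && rc[np] == pc[np])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "seq", start = st, end = st + np - 1L, strand = "-",
        n_mismatch = mm, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_mismatch = integer()))
  res <- do.call(rbind, rows)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# exhaustive greedy one-to-one matcher over explicit distance pairs
bf_match <- function(calls, truth, window) {
  d <- matrix(Inf, nrow(calls), nrow(truth))
  for (i in seq_len(nrow(calls)))
    for (j in seq_len(nrow(truth))) {
      if (calls$chrom[i] != truth$chrom[j]) next
      a <- truth$anchor[j]
      d[i, j] <- if (a >= calls$start[i] && a <= calls$end[i]) 0 else
        min(abs(a - calls$start[i]), abs(a - calls$end[i]))
    }
  d[d > window] <- Inf
  tp <- list()
  while (any(is.finite(d))) {
    # global minimum; ties by truth id then call index
    idx <- which(d == min(d), arr.ind = TRUE)
    idx <- idx[order(truth$id[idx[, 2]], idx[, 1]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    tp[[length(tp) + 1L]] <- data.frame(call_idx = i, truth_id = truth$id[j],
                                        distance_bp = d[i, j])
    d[i, ] <- Inf; d[, j] <- Inf
  }
  tp <- if (length(tp)) do.call(rbind, tp) else
    data.frame(call_idx = integer(), truth_id = character(),
               distance_bp = numeric())
  list(tp = tp,
       fp_calls = setdiff(seq_len(nrow(calls)), tp$call_idx),
       fn_truth = setdiff(truth$id, tp$truth_id))
}

# minimal read-pair row in the table layout filter_pairs() consumes
make_pair <- function(r2_seq, chrom = "chr1", start = 1000L, mapq = 60L,
                      r1_mapped = TRUE, r2_mapped = FALSE,
                      is_duplicate = FALSE, sample_id = "s1",
                      subfamily = "L1HS", id = "p1", strand = "-") {
  data.frame(id = id, sample_id = sample_id, subfamily = subfamily,
             chrom = chrom, start = as.integer(start),
             end = as.integer(start) + 150L, strand = strand,
             mapq = as.integer(mapq), r1_mapped = r1_mapped,
             r2_seq = r2_seq, r2_mapped = r2_mapped, r2_mapq = 0L,
             is_duplicate = is_duplicate, stringsAsFactors = FALSE)
}

# read pairs shaped like filtered cluster input (kept verdicts)
make_kept_pairs <- function(starts, mapq = 60L, chrom = "chr1",
                            sample_id = "s1", subfamily = "L1HS",
                            read_len = 151L) {
  n <- length(starts)
  data.frame(id = sprintf("r%03d", seq_len(n)),
             sample_id = rep_len(sample_id, n),
             subfamily = rep_len(subfamily, n),
             chrom = rep_len(chrom, n),
             start = as.integer(starts),
             end = as.integer(starts) + read_len - 1L,
             strand = rep_len("-", n), mapq = as.integer(rep_len(mapq, n)),
             r1_mapped = rep_len(TRUE, n),
             r2_seq = rep_len(NA_character_, n),
             r2_mapped = rep_len(FALSE, n), r2_mapq = rep_len(0L, n),
             is_duplicate = rep_len(FALSE, n),
             verdict = rep_len("keep", n), reason = rep_len("OK", n),
             primer_class = rep_len("FULL", n),
             te_like_mismatches = rep_len(0L, n),
             te_like_covered = rep_len(1L, n),
             polya_detected = rep_len(TRUE, n), stringsAsFactors = FALSE)
}

# small simulation shared by several files; built once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11L, genome_length_bp = 60000L,
                        n_reference_insertions = 4L,
                        n_nonreference_insertions = 4L,
                        fragments_per_locus = 6L)
      cache <<- simulate_genome_and_insertions(te_profiles(), cfg)
    }
    cache
  }
})
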