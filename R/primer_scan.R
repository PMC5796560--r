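#' Scan a reference sequence for primer match sites
#'
#' Reports every position on either strand whose Hamming distance to the
#' primer is at most `params$primer_scan_max_mismatch`, requiring an exact
#' match at the 3'-ultimate primer base (a mismatch there abolishes
#' priming). Windows containing N never match. Minus-strand matches are
#' reported in forward-strand coordinates with strand `"-"`.
#'
#' @param genome a named `DNAStringSet`, a `DNAString` (treated as one
#'   chromosome named `"seq"`), or a named character vector.
#' @param primer primer sequence over A/C/G/T, written 5' to 3'.
#' @param params a [te_params()] object.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based closed
#'   footprint of the match on the forward strand), `strand`,
#'   `n_mismatch`, sorted by chromosome and start.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrA = paste(rep("ACGT", 50), collapse = "")))
#' scan_primer(g, "ACGTACGTAC")[1:2, ]
#' @export
scan_primer <- function(genome, primer, params = te_params()) {
  if (!is.character(primer) || length(primer) != 1L || nchar(primer) == 0L)
    stop("primer must be a single non-empty string")
  if (grepl("[^ACGT]", primer))
    stop("primer must be over {A,C,G,T}; degenerate bases rejected")
  genome <- .as_dnaset(genome)
  mm_max <- params$primer_scan_max_mismatch
  pr <- Biostrings::DNAString(primer)
  rc <- Biostrings::reverseComplement(pr)
  out <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    if (length(subject) < length(pr)) next
    for (str in c("+", "-")) {
      pat <- if (str == "+") pr else rc
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = mm_max,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      win <- as.character(m)
      pc <- strsplit(as.character(pat), "")[[1]]
      wc <- strsplit(win, "")
      nmis <- vapply(wc, function(w) sum(w != pc), integer(1))
      has_n <- grepl("N", win, fixed = TRUE)
      # 3'-ultimate primer base: last window base on "+", first on "-"
      if (str == "+") {
        three_ok <- vapply(wc, function(w) w[length(w)] == pc[length(pc)],
                           logical(1))
      } else {
        three_ok <- vapply(wc, function(w) w[1L] == pc[1L], logical(1))
      }
      keep <- !has_n & nmis <= mm_max & three_ok
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = BiocGenerics::start(m)[keep],
        end = BiocGenerics::end(m)[keep],
        strand = str, n_mismatch = nmis[keep],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), n_mismatch = integer())
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.as_dnaset <- function(genome) {
  if (methods::is(genome, "DNAString")) {
    genome <- Biostrings::DNAStringSet(list(seq = genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- if (length(genome) == 1L) "seq" else
        paste0("seq", seq_along(genome))
    genome <- Biostrings::DNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)))
    stop("genome DNAStringSet must be named")
  genome
}

#' Build the targeted-locus set from primer matches
#'
#' A targeted locus is a target-primer match paired with a nested-primer
#' match on the same strand, with the nested match 3' of the target match
#' (downstream on "+", upstream on "-") and an inner gap of at most
#' `params$target_pair_max_gap_bp`. Loci overlapping the genome mask or
#' any supplied copy-number-variant interval are removed.
#'
#' @param target_matches,nested_matches match tables from [scan_primer()]
#'   run on the same genome.
#' @param mask optional `"genome_mask"` from [build_mask()].
#' @param cnv_intervals optional intervals (`GRanges` or
#'   chrom/start/end data frame) to exclude.
#' @param params a [te_params()] object.
#' @return Data frame with columns `chrom`, `start`, `end` (locus interval
#'   spanning both matches), `strand`, `gap_bp`, `target_start`,
#'   `nested_start`.
#' @export
build_target_set <- function(target_matches, nested_matches, mask = NULL,
                             cnv_intervals = NULL, params = te_params()) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gap_bp = integer(), target_start = integer(),
                      nested_start = integer())
  if (nrow(target_matches) == 0L || nrow(nested_matches) == 0L)
    return(empty)
  out <- list()
  for (chrom in unique(target_matches$chrom)) {
    for (str in c("+", "-")) {
      tg <- target_matches[target_matches$chrom == chrom &
                             target_matches$strand == str, , drop = FALSE]
      ns <- nested_matches[nested_matches$chrom == chrom &
                             nested_matches$strand == str, , drop = FALSE]
      if (nrow(tg) == 0L || nrow(ns) == 0L) next
      for (i in seq_len(nrow(tg))) {
        if (str == "+") {
          gap <- ns$start - tg$end[i] - 1L
          ok <- ns$start > tg$end[i] & gap <= params$target_pair_max_gap_bp
        } else {
          gap <- tg$start[i] - ns$end - 1L
          ok <- ns$end < tg$start[i] & gap <= params$target_pair_max_gap_bp
        }
        if (!any(ok)) next
        sel <- which(ok)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          start = pmin(tg$start[i], ns$start[sel]),
          end = pmax(tg$end[i], ns$end[sel]),
          strand = str, gap_bp = gap[sel],
          target_start = tg$start[i], nested_start = ns$start[sel],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  loci <- do.call(rbind, out)
  loci <- unique(loci)
  drop <- rep(FALSE, nrow(loci))
  if (!is.null(mask))
    drop <- drop | in_mask(mask, loci$chrom, loci$start, loci$end)
  if (!is.null(cnv_intervals)) {
    cnv <- .as_granges(cnv_intervals)
    if (length(cnv)) {
      q <- GenomicRanges::GRanges(loci$chrom,
                                  IRanges::IRanges(loci$start, loci$end))
      drop <- drop | IRanges::overlapsAny(q, cnv)
    }
  }
  loci <- loci[!drop, , drop = FALSE]
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Find head-to-head (inverted-repeat) primer match pairs
#'
#' Two primer matches on opposite strands face each other head-to-head
#' when the plus-strand match lies upstream of the minus-strand match, so
#' both 3' ends point into the intervening interval. Such loci amplify
#' exponentially from both ends and are artifact-prone. The span is
#' measured between the two 3'-end base positions and must not exceed
#' `params$inverted_max_span_bp`.
#'
#' @param matches a match table from [scan_primer()] (any primer set; rbind
#'   tables to combine primers).
#' @param params a [te_params()] object.
#' @return Data frame with columns `chrom`, `plus_start`, `plus_end`,
#'   `minus_start`, `minus_end`, `span_bp`, sorted by coordinate, one row
#'   per qualifying pair.
#' @export
find_inverted_repeats <- function(matches, params = te_params()) {
  empty <- data.frame(chrom = character(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), span_bp = integer())
  if (nrow(matches) == 0L) return(empty)
  out <- list()
  for (chrom in unique(matches$chrom)) {
    p <- matches[matches$chrom == chrom & matches$strand == "+", , drop = FALSE]
    m <- matches[matches$chrom == chrom & matches$strand == "-", , drop = FALSE]
    if (nrow(p) == 0L || nrow(m) == 0L) next
    for (i in seq_len(nrow(p))) {
      span <- m$start - p$end[i]   # between the two 3'-end bases
      ok <- span >= 0L & span <= params$inverted_max_span_bp
      if (!any(ok)) next
      sel <- which(ok)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, plus_start = p$start[i], plus_end = p$end[i],
        minus_start = m$start[sel], minus_end = m$end[sel],
        span_bp = span[sel], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$plus_start, res$minus_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Derive a subfamily's TE-like sequence from its consensus
#'
#' The TE-like sequence is the consensus sequence downstream (3') of the
#' nested primer, excluding the terminal poly-A tail. The consensus must
#' contain exactly one exact nested-primer match; the terminal poly-A run
#' is stripped when it is at least `params$polya_min_run` bases long.
#'
#' @param consensus_sequence subfamily consensus (character or
#'   `DNAString`).
#' @param nested_primer nested primer string.
#' @param params a [te_params()] object.
#' @return The TE-like sequence as a character string.
#' @examples
#' derive_te_like(paste0("GGGG", "ACGTACGTAC", "TTGCA", strrep("A", 12)),
#'                "ACGTACGTAC")
#' @export
derive_te_like <- function(consensus_sequence, nested_primer,
                           params = te_params()) {
  cons <- as.character(consensus_sequence)
  m <- gregexpr(nested_primer, cons, fixed = TRUE)[[1]]
  if (m[1] == -1L)
    stop("nested primer not found in consensus")
  if (length(m) > 1L)
    stop("nested primer matches consensus more than once")
  after <- substr(cons, m[1] + nchar(nested_primer), nchar(cons))
  run <- attr(regexpr("A*$", after), "match.length")
  if (run >= params$polya_min_run)
    after <- substr(after, 1L, nchar(after) - run)
  if (nchar(after) == 0L)
    stop("empty TE-like sequence: nested primer abuts the poly-A tail")
  after
}
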