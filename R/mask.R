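#' Build a genome accessibility mask
#'
#' Assembly gaps (unassembled poly-N runs) are widened by `gap_flank_bp`
#' on each side; satellite-enriched regions (centromeres, sub-telomeres)
#' are widened by `satellite_window_bp`. Overlapping intervals are merged.
#' Chromosomes in `params$excluded_chroms` (chrY by default) are excluded
#' outright. Calls overlapping the mask are removed from downstream
#' analysis.
#'
#' @param gap_intervals assembly-gap intervals: a `GRanges`, or a data
#'   frame with columns `chrom`, `start`, `end` (1-based, closed).
#' @param satellite_intervals centromere/telomere satellite intervals,
#'   same formats; may be `NULL`.
#' @param params a [te_params()] object.
#' @return An object of class `"genome_mask"` with merged `gap_intervals`
#'   and `satellite_intervals` (`GRanges`) and `excluded_chroms`.
#' @examples
#' m <- build_mask(data.frame(chrom = "chr1", start = 10001, end = 10100))
#' in_mask(m, "chr1", 9600, 9650)
#' @export
build_mask <- function(gap_intervals, satellite_intervals = NULL,
                       params = te_params()) {
  gaps <- .as_granges(gap_intervals)
  sats <- .as_granges(satellite_intervals)
  structure(list(
    gap_intervals       = .expand_merge(gaps, params$gap_flank_bp),
    satellite_intervals = .expand_merge(sats, params$satellite_window_bp),
    excluded_chroms     = params$excluded_chroms
  ), class = "genome_mask")
}

.as_granges <- function(x) {
  if (is.null(x))
    return(GenomicRanges::GRanges())
  if (methods::is(x, "GRanges"))
    return(GenomicRanges::granges(x))
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L)
    return(GenomicRanges::GRanges())
  if (any(x$start > x$end))
    stop("malformed interval: start > end")
  if (any(x$start < 1L))
    stop("malformed interval: coordinates must be >= 1")
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

.expand_merge <- function(gr, flank) {
  if (length(gr) == 0L)
    return(gr)
  s <- pmax(1L, GenomicRanges::start(gr) - flank)  # clamp at chromosome start
  e <- GenomicRanges::end(gr) + flank
  GenomicRanges::reduce(
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr), IRanges::IRanges(s, e)))
}

#' Test intervals for mask membership
#'
#' An interval is masked when its chromosome is excluded or it overlaps a
#' masked interval by at least one base. Chromosomes absent from the mask
#' are silently unmasked.
#'
#' @param mask a `"genome_mask"` from [build_mask()].
#' @param chrom,start,end query interval vectors (1-based, closed), or a
#'   single `GRanges` passed as `chrom` with `start`/`end` missing.
#' @return Logical vector, one element per query.
#' @export
in_mask <- function(mask, chrom, start = NULL, end = NULL) {
  stopifnot(inherits(mask, "genome_mask"))
  if (methods::is(chrom, "GRanges")) {
    q <- chrom
  } else {
    if (length(start) == 0L)
      return(logical(0))
    stopifnot(all(start <= end))
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  }
  hit <- as.character(GenomicRanges::seqnames(q)) %in% mask$excluded_chroms
  for (part in list(mask$gap_intervals, mask$satellite_intervals)) {
    if (length(part)) {
      # harmonise sequence levels so queries on chromosomes absent from
      # the mask are silently unmasked
      lev <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(part))
      GenomeInfoDb::seqlevels(q) <- lev
      GenomeInfoDb::seqlevels(part) <- lev
      hit <- hit | IRanges::overlapsAny(q, part)
    }
  }
  hit
}

#' @export
print.genome_mask <- function(x, ...) {
  cat(sprintf("Genome mask: %d gap interval(s), %d satellite interval(s), excluded: %s\n",
              length(x$gap_intervals), length(x$satellite_intervals),
              paste(x$excluded_chroms, collapse = ",")))
  invisible(x)
}
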