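#' Cluster filtered read-1 anchors by genomic position
#'
#' Single-linkage clustering of read-1 start positions within one
#' sample-by-subfamily library: sorted reads whose start positions are at
#' most `cluster_gap_bp` apart join the same cluster, so retained clusters
#' are separated by more than `cluster_gap_bp`. Start positions are used
#' for linkage because they are the amplification anchor on the flank side
#' and robust to variable read trimming. The cluster interval covers all
#' member read-1 footprints.
#'
#' @param kept_pairs data frame of kept pairs from [filter_pairs()]
#'   (rows with `verdict == "keep"` are used; pass a pre-subset table or
#'   the full filtered table), all from one library.
#' @param params a [te_params()] object.
#' @return Data frame with one row per cluster: `sample_id`,
#'   `subfamily`, `chrom`, `start`, `end`, `read1_count_hq` (members with
#'   MAPQ >= `min_cluster_mapq`), `read1_total`, `read2_mapped_count`,
#'   `polya_count`, and a list column `member_ids`. Ordered by
#'   chromosome then start.
#' @export
cluster_reads <- function(kept_pairs, params = te_params()) {
  if (!is.null(kept_pairs$verdict))
    kept_pairs <- kept_pairs[kept_pairs$verdict == "keep", , drop = FALSE]
  empty <- data.frame(sample_id = character(), subfamily = character(),
                      chrom = character(), start = integer(),
                      end = integer(), read1_count_hq = integer(),
                      read1_total = integer(),
                      read2_mapped_count = integer(),
                      polya_count = integer())
  empty$member_ids <- list()
  if (nrow(kept_pairs) == 0L) return(empty)
  if (length(unique(kept_pairs$sample_id)) > 1L ||
      length(unique(kept_pairs$subfamily)) > 1L)
    stop("cluster_reads expects pairs from a single sample x subfamily library")
  if (is.null(kept_pairs$id))
    kept_pairs$id <- as.character(seq_len(nrow(kept_pairs)))
  out <- list()
  for (chrom in unique(kept_pairs$chrom)) {
    p <- kept_pairs[kept_pairs$chrom == chrom, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(p$start) > params$cluster_gap_bp)))
    for (g in unique(grp)) {
      m <- p[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = m$sample_id[1L], subfamily = m$subfamily[1L],
        chrom = chrom, start = min(m$start), end = max(m$end),
        read1_count_hq = sum(m$mapq >= params$min_cluster_mapq),
        read1_total = nrow(m),
        read2_mapped_count = sum(m$r2_mapped %in% TRUE),
        polya_count = sum(m$polya_detected %in% TRUE),
        stringsAsFactors = FALSE)
      out[[length(out)]]$member_ids <- list(m$id)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply cluster support and span thresholds
#'
#' Retains clusters with at least `min_read1_per_cluster` high-quality
#' read-1 members (MAPQ >= `min_cluster_mapq`) and a cluster interval span
#' of at least `min_cluster_span_bp`. The span floor, set from the read
#' length, rejects degenerate micro-clusters of clipped alignments while
#' a single full-length read footprint passes. Members with
#' `min_report_mapq <= MAPQ < min_cluster_mapq` still contribute to the
#' span and total count but not to the high-quality requirement.
#'
#' @param clusters output of [cluster_reads()].
#' @param params a [te_params()] object.
#' @return The retained subset, order preserved.
#' @export
apply_cluster_thresholds <- function(clusters, params = te_params()) {
  if (nrow(clusters) == 0L) return(clusters)
  span <- clusters$end - clusters$start + 1L
  keep <- clusters$read1_count_hq >= params$min_read1_per_cluster &
    span >= params$min_cluster_span_bp
  res <- clusters[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Remove clusters overlapping the genome mask
#'
#' Clusters whose interval overlaps a masked region by any amount, or
#' whose chromosome is excluded, are removed and returned in an audit
#' table with the mask reason.
#'
#' @param clusters output of [cluster_reads()] or
#'   [apply_cluster_thresholds()].
#' @param mask a `"genome_mask"` from [build_mask()].
#' @return List with `retained` (clusters kept) and `masked` (removed
#'   clusters with an added `mask_reason` column, one of
#'   `"excluded_chrom"` or `"masked_interval"`).
#' @export
apply_mask <- function(clusters, mask) {
  stopifnot(inherits(mask, "genome_mask"))
  if (nrow(clusters) == 0L) {
    masked <- clusters
    masked$mask_reason <- character(0)
    return(list(retained = clusters, masked = masked))
  }
  excl <- clusters$chrom %in% mask$excluded_chroms
  hit <- in_mask(mask, clusters$chrom, clusters$start, clusters$end)
  masked <- clusters[hit, , drop = FALSE]
  masked$mask_reason <- ifelse(excl[hit], "excluded_chrom", "masked_interval")
  retained <- clusters[!hit, , drop = FALSE]
  rownames(retained) <- rownames(masked) <- NULL
  list(retained = retained, masked = masked)
}
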