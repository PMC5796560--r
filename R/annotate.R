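#' Construct an annotation record table
#'
#' Normalises reference TE annotations (RepeatMasker-style, subfamily
#' known) and polymorphic-TE database records (class known, subfamily and
#' strand often absent) into the common table consumed by
#' [classify_clusters()].
#'
#' @param chrom,start,end interval vectors (1-based, closed).
#' @param strand `"+"`, `"-"`, or `"*"` when unknown.
#' @param te_class `"LINE1"` or `"Alu"`.
#' @param subfamily subfamily name, `NA` when unavailable; required for
#'   `source = "reference"`.
#' @param source `"reference"` or `"polyTEdb"`.
#' @param record_id unique record identifiers; generated when missing.
#' @return Data frame of annotation records.
#' @export
annotation_records <- function(chrom, start, end, strand = "*",
                               te_class, subfamily = NA_character_,
                               source = "reference", record_id = NULL) {
  n <- length(chrom)
  rec <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end),
                    strand = rep_len(strand, n),
                    te_class = rep_len(te_class, n),
                    subfamily = rep_len(subfamily, n),
                    source = rep_len(source, n),
                    record_id = if (is.null(record_id))
                      sprintf("rec%05d", seq_len(n)) else record_id,
                    stringsAsFactors = FALSE)
  if (any(rec$end < rec$start)) stop("malformed annotation interval")
  if (!all(rec$source %in% c("reference", "polyTEdb")))
    stop("source must be 'reference' or 'polyTEdb'")
  if (any(rec$source == "reference" & is.na(rec$subfamily)))
    stop("reference records require a subfamily")
  rec
}

#' 3' anchor positions of an annotation record
#'
#' The assay reads out the 3' end of an insertion, so clusters are matched
#' to the annotation's 3' terminus: interval end on "+", interval start on
#' "-". When the strand is unknown both interval ends are returned and
#' both are tested.
#'
#' @param record one annotation record (single-row data frame or list
#'   with `start`, `end`, `strand`).
#' @return Numeric vector of one or two anchor positions.
#' @export
three_prime_anchors <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  switch(as.character(record$strand),
         "+" = record$end,
         "-" = record$start,
         c(record$start, record$end))
}

# distance from a cluster interval to a point anchor: 0 when the anchor
# lies inside the interval, else the gap to the nearer edge
.anchor_distance <- function(start, end, anchor) {
  ifelse(anchor >= start & anchor <= end, 0L,
         pmin(abs(anchor - start), abs(anchor - end)))
}

#' Classify clusters as reference, known non-reference, or novel
#'
#' A cluster is *reference* when a reference-genome TE annotation of the
#' library's targeted subfamily has a 3' anchor within
#' `annotation_window_bp` of the cluster interval; failing that, *known
#' non-reference* when a polymorphic-TE database record of the library's
#' TE class is within the window (subfamily information is often absent
#' from such databases, so only the class is required); otherwise
#' *novel*. A reference annotation of the wrong subfamily inside the
#' window does not produce a reference call; the cluster falls through.
#' Among candidates at one stage, the smallest distance wins, then the
#' lowest record id.
#'
#' @param clusters cluster table from [apply_cluster_thresholds()] /
#'   [apply_mask()].
#' @param records annotation table from [annotation_records()] (reference
#'   and polyTEdb records may be mixed).
#' @param params a [te_params()] object.
#' @param synonyms subfamily synonym groups, see [subfamily_synonyms()].
#' @return The cluster table with appended columns `status`
#'   (`"reference"`, `"known_non_reference"`, `"novel"`),
#'   `matched_record_id` (`NA` for novel) and `distance_bp`.
#' @export
classify_clusters <- function(clusters, records = NULL,
                              params = te_params(),
                              synonyms = subfamily_synonyms()) {
  n <- nrow(clusters)
  status <- rep("novel", n)
  matched <- rep(NA_character_, n)
  dist_bp <- rep(NA_integer_, n)
  if (!is.null(records) && nrow(records) > 0L) {
    class_of <- c("L1HS" = "LINE1", "AluYa5/8" = "Alu", "AluYb8/9" = "Alu")
    for (i in seq_len(n)) {
      lib <- clusters$subfamily[i]
      lib_class <- if (lib %in% names(class_of)) class_of[[lib]] else lib
      syn <- if (lib %in% names(synonyms)) synonyms[[lib]] else lib
      cand <- records[records$chrom == clusters$chrom[i], , drop = FALSE]
      if (nrow(cand) == 0L) next
      d <- vapply(seq_len(nrow(cand)), function(j) {
        min(.anchor_distance(clusters$start[i], clusters$end[i],
                             three_prime_anchors(cand[j, ])))
      }, numeric(1))
      within <- d <= params$annotation_window_bp
      pick <- function(sel) {
        if (!any(sel)) return(NULL)
        idx <- which(sel)
        idx[order(d[idx], cand$record_id[idx])][1L]
      }
      j <- pick(within & cand$source == "reference" & cand$subfamily %in% syn)
      if (!is.null(j)) {
        status[i] <- "reference"
      } else {
        j <- pick(within & cand$source == "polyTEdb" &
                    cand$te_class == lib_class)
        if (!is.null(j)) status[i] <- "known_non_reference"
      }
      if (!is.null(j)) {
        matched[i] <- cand$record_id[j]
        dist_bp[i] <- as.integer(d[j])
      }
    }
  }
  clusters$status <- status
  clusters$matched_record_id <- matched
  clusters$distance_bp <- dist_bp
  clusters
}

#' Write classified calls to TSV and BED
#'
#' Writes `<prefix>.tsv` (all columns) and `<prefix>.bed` (BED6+ with
#' 0-based half-open coordinates, name `sample|subfamily|status`, score =
#' high-quality read-1 count, then the remaining count columns). Rows are
#' sorted by chromosome, start, sample and subfamily. [read_calls()]
#' round-trips the TSV.
#'
#' @param calls output of [classify_clusters()].
#' @param path_prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_calls <- function(calls, path_prefix) {
  ord <- order(calls$chrom, calls$start, calls$sample_id, calls$subfamily)
  calls <- calls[ord, , drop = FALSE]
  flat <- calls
  flat$member_ids <- if (nrow(flat))
    vapply(calls$member_ids, paste, character(1), collapse = ",") else
      character(0)
  tsv <- paste0(path_prefix, ".tsv")
  bed <- paste0(path_prefix, ".bed")
  write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  # header-only files when there are no calls
  writeLines(paste(c("#chrom", "start", "end", "name", "score", "strand",
                     "read1_total", "read2_mapped_count", "polya_count"),
                   collapse = "\t"), bed)
  if (nrow(calls)) {
    bed_df <- data.frame(
      chrom = calls$chrom, start = calls$start - 1L, end = calls$end,
      name = paste(calls$sample_id, calls$subfamily, calls$status, sep = "|"),
      score = calls$read1_count_hq, strand = ".",
      read1_total = calls$read1_total,
      read2_mapped_count = calls$read2_mapped_count,
      polya_count = calls$polya_count)
    write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, append = TRUE)
  }
  invisible(c(tsv = tsv, bed = bed))
}

#' Read calls written by [write_calls()]
#'
#' @param tsv_path path to the `.tsv` file.
#' @return The call table, with `member_ids` restored as a list column.
#' @export
read_calls <- function(tsv_path) {
  df <- read.table(tsv_path, sep = "\t", header = TRUE,
                   colClasses = NA, stringsAsFactors = FALSE,
                   check.names = FALSE)
  # enforce column types (all-NA or empty columns otherwise read as logical)
  int_cols <- c("start", "end", "read1_count_hq", "read1_total",
                "read2_mapped_count", "polya_count", "distance_bp")
  chr_cols <- c("sample_id", "subfamily", "chrom", "status",
                "matched_record_id")
  for (cc in intersect(int_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
  for (cc in intersect(chr_cols, names(df))) df[[cc]] <- as.character(df[[cc]])
  if (nrow(df)) {
    df$member_ids <- strsplit(as.character(df$member_ids), ",", fixed = TRUE)
  } else {
    df$member_ids <- list()
  }
  df
}
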