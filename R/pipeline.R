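#' Run the calling pipeline for one sample
#'
#' Orchestrates, per sample-by-subfamily library: pair filtering
#' ([filter_pairs()]), positional clustering ([cluster_reads()]),
#' support/span thresholds ([apply_cluster_thresholds()]), genome
#' masking ([apply_mask()]) and annotation-based classification
#' ([classify_clusters()]). Libraries may be given as alignment file
#' paths or as in-memory pair tables (e.g. straight from
#' [simulate_library()]).
#'
#' @param libraries either a named character vector of SAM/BAM paths
#'   (names = subfamily), or a pair table covering one or more
#'   subfamilies of one sample.
#' @param sample_id sample identifier (ignored for pair tables, which
#'   carry their own).
#' @param profiles profiles from [te_profiles()].
#' @param params a [te_params()] object.
#' @param mask optional `"genome_mask"`.
#' @param annotations optional annotation table from
#'   [annotation_records()]; without it every retained cluster is
#'   classified novel.
#' @param out_dir optional output directory; when given, classified
#'   calls (`calls.tsv`/`calls.bed`), per-library filter summaries
#'   (`filter_summary.tsv`) and the masked-cluster audit
#'   (`masked_audit.tsv`) are written there.
#' @return List with `calls` (classified call table across libraries),
#'   `summaries` (per-library filter summaries), `masked` (audit of
#'   mask-removed clusters) and `filtered` (per-library filtered pair
#'   tables).
#' @export
run_call <- function(libraries, sample_id = "sample1",
                     profiles = te_profiles(), params = te_params(),
                     mask = NULL, annotations = NULL, out_dir = NULL) {
  if (is.character(libraries)) {
    if (is.null(names(libraries)))
      stop("library paths must be named by subfamily")
    missing_profile <- setdiff(names(libraries), names(profiles))
    if (length(missing_profile))
      stop("no subfamily profile for library: ",
           paste(missing_profile, collapse = ", "))
    tabs <- lapply(names(libraries), function(sf)
      read_alignments(libraries[[sf]], sample_id, sf))
    names(tabs) <- names(libraries)
  } else {
    stopifnot(is.data.frame(libraries))
    tabs <- split(libraries, libraries$subfamily)
  }
  calls <- list(); summaries <- list(); masked <- list(); filtered <- list()
  for (sf in names(tabs)) {
    if (!sf %in% names(profiles))
      stop("no subfamily profile for library: ", sf)
    flt <- filter_pairs(tabs[[sf]], profiles[[sf]], params)
    filtered[[sf]] <- flt
    summaries[[sf]] <- filter_summary(flt)
    cl <- cluster_reads(flt[flt$verdict == "keep", , drop = FALSE], params)
    cl <- apply_cluster_thresholds(cl, params)
    if (!is.null(mask)) {
      mk <- apply_mask(cl, mask)
      cl <- mk$retained
      if (nrow(mk$masked)) masked[[sf]] <- mk$masked
    }
    calls[[sf]] <- classify_clusters(cl, annotations, params)
  }
  calls <- if (length(calls)) do.call(rbind, unname(calls)) else
    classify_clusters(cluster_reads(data.frame()), annotations, params)
  rownames(calls) <- NULL
  masked <- if (length(masked)) do.call(rbind, unname(masked)) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(calls, file.path(out_dir, "calls"))
    sm <- do.call(rbind, lapply(names(summaries), function(sf) {
      s <- summaries[[sf]]
      data.frame(subfamily = sf, reason = names(s$reason_counts),
                 count = as.integer(s$reason_counts))
    }))
    write.table(sm, file.path(out_dir, "filter_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(masked)) {
      aud <- masked
      aud$member_ids <- vapply(aud$member_ids, paste, character(1),
                               collapse = ",")
      write.table(aud, file.path(out_dir, "masked_audit.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  list(calls = calls, summaries = summaries, masked = masked,
       filtered = filtered)
}

#' Evaluate calls against a truth resource
#'
#' Thin dispatcher over the evaluation module. Modes:
#' \describe{
#'   \item{`reference`}{calls vs a reference truth set, subfamily-level
#'     matching.}
#'   \item{`mei`}{calls vs a polymorphic-insertion truth set,
#'     class-level matching (subfamily designations are often absent).}
#'   \item{`trio`}{proband calls vs the parental truth set built with
#'     [build_parental_truth()]; proband novel calls absent from both
#'     parents (at single-read evidence) are de novo and count as FP.}
#'   \item{`longread`}{counts spanning long reads with exact TE-like
#'     matches per call.}
#' }
#'
#' @param calls classified call table.
#' @param truth mode-dependent: a truth table (`reference`/`mei`), a
#'   list with `parent1_clusters`, `parent2_clusters`, `parent1_pairs`,
#'   `parent2_pairs` (`trio`), or a long-read table (`longread`).
#' @param mode evaluation mode.
#' @param params a [te_params()] object.
#' @param profiles profiles (needed for `longread`).
#' @return Mode-dependent: an `"eval_result"` plus match detail, a trio
#'   result list, or a per-call support-count vector.
#' @export
run_evaluate <- function(calls, truth,
                         mode = c("reference", "mei", "trio", "longread"),
                         params = te_params(), profiles = te_profiles()) {
  mode <- match.arg(mode)
  if (mode %in% c("reference", "mei")) {
    lev <- if (mode == "reference") "subfamily" else "class"
    m <- match_calls_to_truth(calls, truth, params, lev)
    res <- precision_recall(nrow(m$tp), length(m$fp_calls),
                            length(m$fn_truth))
    return(list(result = res, matches = m))
  }
  if (mode == "trio") {
    ptruth <- build_parental_truth(truth$parent1_clusters,
                                   truth$parent2_clusters, params)
    m <- match_calls_to_truth(calls, ptruth, params, "subfamily")
    novel <- calls[calls$status == "novel" &
                     seq_len(nrow(calls)) %in% m$fp_calls, , drop = FALSE]
    dn <- classify_proband_novel(novel, truth$parent1_pairs,
                                 truth$parent2_pairs, params)
    res <- precision_recall(nrow(m$tp), nrow(dn$de_novo),
                            length(m$fn_truth))
    return(list(result = res, matches = m, parental_truth = ptruth,
                inherited = dn$inherited, de_novo = dn$de_novo))
  }
  # longread
  counts <- vapply(seq_len(nrow(calls)), function(i)
    validate_with_long_reads(calls[i, ], truth,
                             profiles[[calls$subfamily[i]]]),
    integer(1))
  data.frame(call_idx = seq_len(nrow(calls)), support_count = counts,
             validated = counts >= 1L)
}
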