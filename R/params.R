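#' Pipeline parameters
#'
#' Returns the full parameter set controlling filtering, clustering,
#' masking, annotation and evaluation, with defaults matching the published
#' protocol where the protocol states a value. Any parameter may be
#' overridden by name.
#'
#' @param ... named overrides of individual parameters.
#'
#' @details
#' Key parameters and their defaults:
#' \describe{
#'   \item{primer_partial_min_matches / primer_prefix_len}{a read-2 prefix
#'     matching at least 7 of the first 10 nested-primer bases counts as a
#'     "partial" (discernible) primer match; below that the pair is genomic
#'     background.}
#'   \item{min_report_mapq}{read-1 alignments below this MAPQ (default 1,
#'     i.e. MAPQ 0) are removed after the primer/TE-like requirements.}
#'   \item{min_cluster_mapq}{read-1 members must have MAPQ >= 3 to count
#'     toward the per-cluster read support threshold.}
#'   \item{cluster_gap_bp}{minimum inter-distance (200 bp) between
#'     neighbouring clusters; read-1 start positions closer than this are
#'     linked into one cluster.}
#'   \item{min_cluster_span_bp}{minimum cluster interval span (100 bp),
#'     below the 151 bp read length so one clean read footprint passes.}
#'   \item{min_read1_per_cluster}{minimum high-quality read-1 support
#'     (default 2) to report a cluster.}
#'   \item{annotation_window_bp}{window (600 bp) around a TE 3' end within
#'     which a cluster is considered to hit that annotation or truth record.}
#'   \item{gap_flank_bp, satellite_window_bp, excluded_chroms}{genome mask:
#'     assembly gaps widened by 500 bp, centromere/telomere satellite
#'     regions by 1 Mb, and chrY excluded outright.}
#'   \item{parental_window_bp}{window (100 bp) for matching insertions
#'     between members of a trio.}
#'   \item{primer_scan_max_mismatch}{reference primer scanning allows at
#'     most 1 mismatch, never at the 3'-ultimate primer base.}
#'   \item{target_pair_max_gap_bp}{a target-primer and nested-primer match
#'     define a targeted locus when at most 200 bp apart in proper order
#'     and orientation.}
#'   \item{inverted_max_span_bp}{head-to-head primer match pairs within
#'     1 kb are reported as inverted-repeat (artifact-prone) loci.}
#'   \item{polya_min_run, polya_max_nonA}{poly-A tail corroboration: a run
#'     of >= 8 bases with at most 1 non-A downstream of the TE-like
#'     region. Annotation only; never changes a filter verdict.}
#' }
#'
#' @return A named list of class `"te_params"`.
#' @examples
#' p <- te_params(cluster_gap_bp = 300)
#' p$cluster_gap_bp
#' @export
te_params <- function(...) {
  p <- list(
    primer_partial_min_matches = 7L,
    primer_prefix_len          = 10L,
    min_report_mapq            = 1L,
    min_cluster_mapq           = 3L,
    cluster_gap_bp             = 200L,
    min_cluster_span_bp        = 100L,
    min_read1_per_cluster      = 2L,
    annotation_window_bp       = 600L,
    gap_flank_bp               = 500L,
    satellite_window_bp        = 1000000L,
    excluded_chroms            = "chrY",
    parental_window_bp         = 100L,
    primer_scan_max_mismatch   = 1L,
    target_pair_max_gap_bp     = 200L,
    inverted_max_span_bp       = 1000L,
    polya_min_run              = 8L,
    polya_max_nonA             = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  num <- setdiff(names(p), "excluded_chroms")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number")
    p[[nm]] <- as.integer(v)
  }
  if (p$primer_partial_min_matches > p$primer_prefix_len)
    stop("primer_partial_min_matches must not exceed primer_prefix_len")
  p$excluded_chroms <- as.character(p$excluded_chroms)
  class(p) <- "te_params"
  p
}

#' Targeted subfamily profiles
#'
#' One profile per targeted subfamily: the PCR target primer, the nested
#' primer that starts read 2, the subfamily's TE-like sequence (consensus
#' bases between the nested primer and the poly-A tail) and the maximum
#' number of mismatches to the TE-like sequence tolerated in a retained
#' read. The three default profiles target L1HS, AluYa5/8 and AluYb8/9
#' with TE-like lengths of 8, 37 and 29 nt and mismatch caps of 3, 10 and
#' 10 respectively, mirroring the assay design. The primer and TE-like
#' sequences shipped here are synthetic stand-ins with the assay's lengths
#' and structure (the assay's oligo sequences are not redistributed);
#' supply your own profiles via this constructor for real libraries.
#'
#' @param profiles optional list of profiles built with [te_profile()];
#'   default is the three shipped synthetic profiles.
#' @return Named list of `"te_profile"` objects.
#' @examples
#' pf <- te_profiles()
#' vapply(pf, function(p) nchar(p$te_like), integer(1))
#' @export
te_profiles <- function(profiles = NULL) {
  if (!is.null(profiles)) {
    stopifnot(all(vapply(profiles, inherits, logical(1), "te_profile")))
    names(profiles) <- vapply(profiles, `[[`, character(1), "name")
    return(profiles)
  }
  # Synthetic default profiles. The two Alu subfamilies share one target
  # primer, as in the multiplexed assay (one target primer per TE class).
  alu_target <- "GTCCGATTACGGAAGTCTGC"
  lst <- list(
    te_profile(
      name = "L1HS", te_class = "LINE1",
      target_primer = "AGGGTTACGCAGATTGCTCA",
      nested_primer = "CCTAGTGCAGTAACGATTGG",
      te_like = "TCAGGCAT",
      max_te_like_mismatches = 3L,
      index_tag = "i7-L1"),
    te_profile(
      name = "AluYa5/8", te_class = "Alu",
      target_primer = alu_target,
      nested_primer = "TTGACGCATCGGATAGCACT",
      te_like = "ACGGTTCAGCATTGAGCCTAGACGTTCACTGGAATCC",
      max_te_like_mismatches = 10L,
      index_tag = "i7-Ya"),
    te_profile(
      name = "AluYb8/9", te_class = "Alu",
      target_primer = alu_target,
      nested_primer = "GCTTAGGATCCGTACAGTGA",
      te_like = "GATCCACTAGGCTTACGGAGTCAAGTGCA",
      max_te_like_mismatches = 10L,
      index_tag = "i7-Yb")
  )
  names(lst) <- vapply(lst, `[[`, character(1), "name")
  lst
}

#' Construct a single subfamily profile
#'
#' @param name subfamily name (e.g. `"L1HS"`).
#' @param te_class TE class, `"LINE1"` or `"Alu"`.
#' @param target_primer,nested_primer,te_like DNA strings over A/C/G/T.
#' @param max_te_like_mismatches non-negative mismatch cap for read
#'   retention.
#' @param index_tag opaque library index identifier.
#' @return A list of class `"te_profile"`.
#' @export
te_profile <- function(name, te_class = c("LINE1", "Alu"),
                       target_primer, nested_primer, te_like,
                       max_te_like_mismatches, index_tag = name) {
  te_class <- match.arg(te_class)
  for (s in list(target_primer, nested_primer, te_like)) {
    if (!is.character(s) || length(s) != 1L || nchar(s) == 0L)
      stop("primer and TE-like sequences must be non-empty strings")
    if (grepl("[^ACGT]", s))
      stop("sequences must be over {A,C,G,T}; degenerate bases rejected")
  }
  max_te_like_mismatches <- as.integer(max_te_like_mismatches)
  if (is.na(max_te_like_mismatches) || max_te_like_mismatches < 0)
    stop("max_te_like_mismatches must be a non-negative integer")
  structure(list(
    name = name, te_class = te_class,
    target_primer = target_primer, nested_primer = nested_primer,
    te_like = te_like, max_te_like_mismatches = max_te_like_mismatches,
    index_tag = index_tag), class = "te_profile")
}

#' Subfamily synonym groups for annotation matching
#'
#' RepeatMasker-style annotations name individual subfamilies (AluYa5,
#' AluYa8, ...) while each library targets a subfamily group. A reference
#' annotation satisfies a library when its subfamily belongs to the
#' library's synonym group.
#'
#' @return Named list mapping library subfamily name to the character
#'   vector of acceptable annotation subfamily names.
#' @export
subfamily_synonyms <- function() {
  list(
    "L1HS"     = c("L1HS", "L1Ta"),
    "AluYa5/8" = c("AluYa5/8", "AluYa5", "AluYa8"),
    "AluYb8/9" = c("AluYb8/9", "AluYb8", "AluYb9")
  )
}

#' @export
print.te_params <- function(x, ...) {
  cat("Pipeline parameters:\n")
  for (nm in names(x))
    cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}

#' @export
print.te_profile <- function(x, ...) {
  cat(sprintf("Subfamily profile %s (%s): nested primer %d nt, TE-like %d nt, mismatch cap %d\n",
              x$name, x$te_class, nchar(x$nested_primer), nchar(x$te_like),
              x$max_te_like_mismatches))
  invisible(x)
}
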