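#' Simulation configuration
#'
#' Parameters of the synthetic targeted-library generator. Defaults
#' emulate the assay's stated library geometry: ~300 bp sheared insert
#' size, 2 x 151 bp paired-end reads. One chromosome is simulated per
#' targeted subfamily, with insertion loci spaced at least
#' `min_locus_spacing_bp` apart so that clusters from distinct loci never
#' merge.
#'
#' @param genome_length_bp base genome length per simulated chromosome.
#' @param n_reference_insertions,n_nonreference_insertions planted
#'   insertions per subfamily present in (reference + donor) versus
#'   (donor only).
#' @param fragment_mean_bp,fragment_sd_bp normal fragment-length model.
#' @param read_length paired-end read length.
#' @param fragments_per_locus sequenced fragments per planted locus.
#' @param background_fraction fraction of library pairs that are genomic
#'   background (no primer on read 2).
#' @param headtohead_fraction fraction of pairs from head-to-head
#'   inverted-repeat artifacts (primer evidence at both ends; read 1
#'   maps with MAPQ 0).
#' @param substitution_error_rate per-base substitution rate applied to
#'   the TE-like portion of read 2.
#' @param polya_tail_len length of the emitted poly-A tail.
#' @param min_locus_spacing_bp minimum spacing between planted loci.
#' @param seed integer seed fixing all randomness.
#' @return A named list of class `"sim_config"`.
#' @export
sim_config <- function(genome_length_bp = 100000L,
                       n_reference_insertions = 10L,
                       n_nonreference_insertions = 10L,
                       fragment_mean_bp = 300L, fragment_sd_bp = 30L,
                       read_length = 151L, fragments_per_locus = 10L,
                       background_fraction = 0.3,
                       headtohead_fraction = 0.02,
                       substitution_error_rate = 0,
                       polya_tail_len = 16L,
                       min_locus_spacing_bp = 2000L,
                       seed = 1L) {
  cfg <- list(genome_length_bp = as.integer(genome_length_bp),
              n_reference_insertions = as.integer(n_reference_insertions),
              n_nonreference_insertions = as.integer(n_nonreference_insertions),
              fragment_mean_bp = as.integer(fragment_mean_bp),
              fragment_sd_bp = as.integer(fragment_sd_bp),
              read_length = as.integer(read_length),
              fragments_per_locus = as.integer(fragments_per_locus),
              background_fraction = background_fraction,
              headtohead_fraction = headtohead_fraction,
              substitution_error_rate = substitution_error_rate,
              polya_tail_len = as.integer(polya_tail_len),
              min_locus_spacing_bp = as.integer(min_locus_spacing_bp),
              seed = as.integer(seed))
  for (f in c("background_fraction", "headtohead_fraction",
              "substitution_error_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be in [0,1]")
  if (cfg$background_fraction + cfg$headtohead_fraction >= 1)
    stop("background_fraction + headtohead_fraction must be < 1")
  if (cfg$read_length > cfg$fragment_mean_bp + 4L * cfg$fragment_sd_bp)
    stop("read_length must not exceed fragment_mean_bp + 4*fragment_sd_bp")
  class(cfg) <- "sim_config"
  cfg
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.te_consensus <- function(profile, config) {
  paste0(profile$target_primer, profile$nested_primer, profile$te_like,
         strrep("A", config$polya_tail_len))
}

#' Simulate a reference genome, a donor genome and planted insertions
#'
#' Plants, per targeted subfamily on its own chromosome,
#' `n_reference_insertions` TE copies present in both the reference and
#' the donor, and `n_nonreference_insertions` copies present only in the
#' donor. The planted TE is the profile's consensus (target primer,
#' nested primer, TE-like sequence, poly-A tail) so every stage of the
#' pipeline — primer scanning, read filtering, clustering, annotation and
#' evaluation — sees the structure it expects, with exact 3' junction
#' coordinates recorded as ground truth. Loci are kept clear of
#' chromosome ends, so the simulated genomes are mask-free by
#' construction.
#'
#' @param profiles profiles from [te_profiles()].
#' @param config a [sim_config()] object.
#' @return A list of class `"te_sim"`: `reference` and `donor`
#'   (`DNAStringSet`), `truth` (data frame: `id`, `chrom`, `subfamily`,
#'   `type`, `te_start`, `anchor` (3' terminal position in reference
#'   coordinates), `flank_start`, `donor_anchor`) and `config`.
#' @export
simulate_genome_and_insertions <- function(profiles = te_profiles(),
                                           config = sim_config()) {
  set.seed(config$seed)
  margin <- 1500L
  ref <- donor <- character(0)
  truth <- list()
  for (k in seq_along(profiles)) {
    pf <- profiles[[k]]
    chrom <- paste0("chr", k)
    L <- config$genome_length_bp
    n <- config$n_reference_insertions + config$n_nonreference_insertions
    cons <- .te_consensus(pf, config)
    tlen <- nchar(cons)
    spacing <- config$min_locus_spacing_bp
    slack <- L - 2L * margin - spacing * (n - 1L)
    if (slack < n)
      stop("insertions requested beyond genome capacity (minimum spacing ",
           spacing, " bp)")
    base <- .random_dna(L)
    pos <- margin + spacing * (0:(n - 1L)) + sort(sample.int(slack, n))
    type <- sample(c(rep("reference", config$n_reference_insertions),
                     rep("nonreference", config$n_nonreference_insertions)))
    ref_pieces <- donor_pieces <- character(0)
    prev <- 1L; ref_off <- 0L; donor_off <- 0L
    for (i in seq_len(n)) {
      p <- pos[i]
      flank_piece <- substr(base, prev, p - 1L)
      ref_pieces <- c(ref_pieces, flank_piece)
      donor_pieces <- c(donor_pieces, flank_piece)
      donor_pieces <- c(donor_pieces, cons)
      is_ref <- type[i] == "reference"
      if (is_ref) ref_pieces <- c(ref_pieces, cons)
      te_start <- if (is_ref) p + ref_off else NA_integer_
      anchor <- if (is_ref) p + ref_off + tlen - 1L else p + ref_off - 1L
      truth[[length(truth) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%02d", chrom, if (is_ref) "ref" else "nonref", i),
        chrom = chrom, subfamily = pf$name, type = type[i],
        te_start = te_start, anchor = anchor,
        flank_start = anchor + 1L,
        donor_anchor = p + donor_off + tlen - 1L,
        stringsAsFactors = FALSE)
      if (is_ref) ref_off <- ref_off + tlen
      donor_off <- donor_off + tlen
      prev <- p
    }
    ref_pieces <- c(ref_pieces, substr(base, prev, L))
    donor_pieces <- c(donor_pieces, substr(base, prev, L))
    ref[chrom] <- paste(ref_pieces, collapse = "")
    donor[chrom] <- paste(donor_pieces, collapse = "")
  }
  structure(list(reference = Biostrings::DNAStringSet(ref),
                 donor = Biostrings::DNAStringSet(donor),
                 truth = do.call(rbind, truth),
                 config = config), class = "te_sim")
}

#' @export
print.te_sim <- function(x, ...) {
  cat(sprintf("Simulated genome: %d chromosome(s), %d planted insertion(s) (%d reference, %d non-reference)\n",
              length(x$reference), nrow(x$truth),
              sum(x$truth$type == "reference"),
              sum(x$truth$type == "nonreference")))
  invisible(x)
}

#' Simulate a set of targeted libraries from a simulated genome
#'
#' For every planted locus, emits `fragments_per_locus` read pairs
#' spanning the 3' junction: read 2 is the nested primer, the TE-like
#' sequence (mutated at `substitution_error_rate`), the poly-A tail and
#' as much downstream flank as the read length allows; read 1 is the
#' reverse-complemented unique flank at the far end of the fragment.
#' Idealized alignments are emitted directly (no aligner needed): read 1
#' at its true reference coordinate with MAPQ 60; read 2 mapped at the
#' TE with a low MAPQ (0-5) for reference loci, and unmapped for
#' non-reference loci, mirroring the unreliable mapping of reads from
#' insertions absent from the reference. Background pairs (random read 2,
#' no primer) and head-to-head artifact pairs (primer evidence at both
#' ends, read-1 MAPQ 0) are mixed in at the configured fractions.
#'
#' @param sim a `"te_sim"` from [simulate_genome_and_insertions()].
#' @param profiles profiles from [te_profiles()].
#' @param sample_id sample identifier stamped on every pair.
#' @param truth truth subset to sequence; defaults to all planted loci.
#'   Subsetting lets one simulate individuals carrying different
#'   insertion complements (e.g. trios) on the same genome.
#' @param seed seed for fragment-level randomness; defaults to the
#'   configuration seed.
#' @return Data frame with one row per pair: `id`, `sample_id`,
#'   `subfamily`, `chrom`, `start`, `end`, `strand`, `mapq`,
#'   `r1_mapped`, `r1_seq`, `r2_seq`, `r2_mapped`, `r2_mapq`, `r2_pos`,
#'   `is_duplicate`, `truth_id`, `frag_class`, `fragment_len`.
#' @export
simulate_library <- function(sim, profiles = te_profiles(),
                             sample_id = "sample1", truth = sim$truth,
                             seed = sim$config$seed) {
  set.seed(seed)
  config <- sim$config
  refchr <- as.character(sim$reference)
  rl <- config$read_length
  rows <- list()
  for (pf in profiles) {
    loci <- truth[truth$subfamily == pf$name, , drop = FALSE]
    chrom_set <- unique(sim$truth$chrom[sim$truth$subfamily == pf$name])
    te_part <- nchar(pf$nested_primer) + nchar(pf$te_like) +
      config$polya_tail_len
    tl_chars <- strsplit(pf$te_like, "")[[1]]
    n_on <- nrow(loci) * config$fragments_per_locus
    for (i in seq_len(nrow(loci))) {
      fs <- loci$flank_start[i]
      chrom <- loci$chrom[i]
      nf <- config$fragments_per_locus
      f <- as.integer(pmax(round(rnorm(nf, config$fragment_mean_bp,
                                       config$fragment_sd_bp)),
                           te_part + rl))
      fl <- f - te_part
      r2 <- character(nf)
      for (r in seq_len(nf)) {
        tl <- tl_chars
        if (config$substitution_error_rate > 0) {
          hit <- runif(length(tl)) < config$substitution_error_rate
          if (any(hit))
            tl[hit] <- vapply(tl[hit], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        }
        core <- paste0(pf$nested_primer, paste(tl, collapse = ""),
                       strrep("A", config$polya_tail_len))
        need <- rl - nchar(core)
        r2[r] <- if (need > 0)
          paste0(core, substr(refchr[[chrom]], fs, fs + need - 1L)) else
            substr(core, 1L, rl)
      }
      r1_start <- fs + fl - rl
      is_ref <- loci$type[i] == "reference"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, subfamily = pf$name, chrom = chrom,
        start = r1_start, end = r1_start + rl - 1L, strand = "-",
        mapq = 60L, r1_mapped = TRUE,
        r1_seq = NA_character_,   # filled vectorised below
        r2_seq = r2, r2_mapped = is_ref,
        r2_mapq = if (is_ref) sample(0:5, nf, replace = TRUE) else 0L,
        r2_pos = if (is_ref) loci$te_start[i] else NA_integer_,
        is_duplicate = FALSE, truth_id = loci$id[i],
        frag_class = "ontarget", fragment_len = f,
        stringsAsFactors = FALSE)
    }
    # background and head-to-head artifact pairs for this library
    denom <- 1 - config$background_fraction - config$headtohead_fraction
    n_bg <- round(n_on * config$background_fraction / denom)
    n_h2h <- round(n_on * config$headtohead_fraction / denom)
    chrom <- chrom_set[1L]
    L_ref <- nchar(refchr[[chrom]])
    if (n_bg > 0) {
      st <- sample.int(L_ref - rl, n_bg, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, subfamily = pf$name, chrom = chrom,
        start = st, end = st + rl - 1L,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        mapq = 60L, r1_mapped = TRUE,
        r1_seq = substring(refchr[[chrom]], st, st + rl - 1L),
        r2_seq = vapply(seq_len(n_bg), function(b) .random_dna(rl),
                        character(1)),
        r2_mapped = TRUE, r2_mapq = sample(10:60, n_bg, replace = TRUE),
        r2_pos = st, is_duplicate = FALSE, truth_id = NA_character_,
        frag_class = "background", fragment_len = NA_integer_,
        stringsAsFactors = FALSE)
    }
    if (n_h2h > 0) {
      h2h_core <- paste0(pf$nested_primer, pf$te_like,
                         strrep("A", config$polya_tail_len))
      st <- sample.int(L_ref - rl, n_h2h, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, subfamily = pf$name, chrom = chrom,
        start = st, end = st + rl - 1L, strand = "+", mapq = 0L,
        r1_mapped = TRUE,
        r1_seq = substring(refchr[[chrom]], st, st + rl - 1L),
        r2_seq = vapply(seq_len(n_h2h), function(b)
          substr(paste0(h2h_core, .random_dna(rl)), 1L, rl), character(1)),
        r2_mapped = TRUE, r2_mapq = 0L, r2_pos = st,
        is_duplicate = FALSE, truth_id = NA_character_,
        frag_class = "headtohead", fragment_len = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  # read 1 is sequenced from the minus strand of the flank; fill in one
  # vectorised reverse-complement pass
  ont <- which(pairs$frag_class == "ontarget")
  if (length(ont)) {
    fwd <- substring(refchr[pairs$chrom[ont]], pairs$start[ont],
                     pairs$end[ont])
    pairs$r1_seq[ont] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)))
  }
  pairs <- cbind(id = sprintf("%s_p%06d", sample_id, seq_len(nrow(pairs))),
                 pairs, stringsAsFactors = FALSE)
  pairs
}

#' Reference TE annotations of a simulated genome
#'
#' Annotation records (source `"reference"`) for the planted insertions
#' present in the simulated reference, for use with
#' [classify_clusters()].
#'
#' @param sim a `"te_sim"` object.
#' @param profiles profiles from [te_profiles()].
#' @return Annotation table from [annotation_records()].
#' @export
reference_annotations <- function(sim, profiles = te_profiles()) {
  tr <- sim$truth[sim$truth$type == "reference", , drop = FALSE]
  cls <- vapply(tr$subfamily, function(s) profiles[[s]]$te_class, character(1))
  annotation_records(tr$chrom, tr$te_start, tr$anchor, "+", cls,
                     tr$subfamily, "reference", tr$id)
}

#' Truth records of a simulated genome
#'
#' @param sim a `"te_sim"` object.
#' @param type which planted loci to convert: `"nonreference"`,
#'   `"reference"` or `"all"`.
#' @return Truth table from [truth_records()].
#' @export
sim_truth <- function(sim, type = c("nonreference", "reference", "all")) {
  type <- match.arg(type)
  tr <- sim$truth
  if (type != "all") tr <- tr[tr$type == type, , drop = FALSE]
  src <- ifelse(tr$type == "reference", "reference_truth", "mei_truth")
  truth_records(tr$chrom, tr$anchor, tr$subfamily,
                .library_class(tr$subfamily), src, tr$id)
}
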