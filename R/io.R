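#' Write a simulated library fixture to disk
#'
#' Writes, per sample-by-subfamily library, a coordinate-sorted SAM file
#' and R1/R2 FASTQ files; plus the reference FASTA, a truth BED
#' (0-based half-open, one record per planted locus anchored at its 3'
#' terminal position) and a configuration snapshot TSV. All outputs are
#' plain text, re-readable by [read_alignments()] and standard tools.
#'
#' @param pairs pair table from [simulate_library()].
#' @param sim the `"te_sim"` the pairs were simulated from.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of written paths (`sam`, `fastq1`,
#'   `fastq2` keyed by library, plus `reference`, `truth`, `config`).
#' @export
write_fixture <- function(pairs, sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(sim$reference, ref_path)
  truth_path <- file.path(out_dir, "truth.bed")
  tr <- sim$truth
  write.table(data.frame(tr$chrom, tr$anchor - 1L, tr$anchor,
                         paste(tr$subfamily, tr$type, tr$id, sep = "|"),
                         0L, "+"),
              truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cfg_path <- file.path(out_dir, "config.tsv")
  cfg <- sim$config
  write.table(data.frame(parameter = names(cfg),
                         value = vapply(cfg, function(v)
                           paste(v, collapse = ","), character(1))),
              cfg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  chrom_len <- setNames(Biostrings::width(sim$reference),
                        names(sim$reference))
  out <- list(reference = ref_path, truth = truth_path, config = cfg_path)
  libs <- unique(pairs[, c("sample_id", "subfamily")])
  for (k in seq_len(nrow(libs))) {
    p <- pairs[pairs$sample_id == libs$sample_id[k] &
                 pairs$subfamily == libs$subfamily[k], , drop = FALSE]
    tag <- paste0(libs$sample_id[k], "_", gsub("[^A-Za-z0-9]", "", libs$subfamily[k]))
    sam <- file.path(out_dir, paste0(tag, ".sam"))
    .write_sam(p, chrom_len, sam)
    fq1 <- file.path(out_dir, paste0(tag, "_R1.fastq"))
    fq2 <- file.path(out_dir, paste0(tag, "_R2.fastq"))
    r1 <- Biostrings::DNAStringSet(setNames(p$r1_seq, p$id))
    r2 <- Biostrings::DNAStringSet(setNames(p$r2_seq, p$id))
    Biostrings::writeXStringSet(r1, fq1, format = "fastq")
    Biostrings::writeXStringSet(r2, fq2, format = "fastq")
    out[[paste0("sam_", tag)]] <- sam
    out[[paste0("fastq1_", tag)]] <- fq1
    out[[paste0("fastq2_", tag)]] <- fq2
  }
  invisible(out)
}

# Emit idealized alignments as coordinate-sorted SAM.
.write_sam <- function(pairs, chrom_len, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), chrom_len))
  recs <- pos <- integer(0)
  lines <- character(0)
  ord_chrom <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    dup <- if (isTRUE(p$is_duplicate)) 1024L else 0L
    rl <- nchar(p$r2_seq)
    qual <- strrep("I", rl)
    # read 1: mapped at its true coordinate
    f1 <- 1L + 64L + dup +
      (if (p$strand == "-") 16L else 0L) +
      (if (!isTRUE(p$r2_mapped)) 8L else 0L)
    seq1 <- if (p$strand == "-") .revcomp(p$r1_seq) else p$r1_seq
    pnext1 <- if (isTRUE(p$r2_mapped)) p$r2_pos else p$start
    lines <- c(lines, paste(p$id, f1, p$chrom, p$start, p$mapq,
                            paste0(nchar(p$r1_seq), "M"), "=", pnext1, 0L,
                            seq1, strrep("I", nchar(p$r1_seq)), sep = "\t"))
    ord_chrom <- c(ord_chrom, match(p$chrom, names(chrom_len)))
    pos <- c(pos, p$start)
    # read 2
    if (isTRUE(p$r2_mapped)) {
      f2 <- 1L + 128L + dup + (if (p$strand == "-") 32L else 0L)
      lines <- c(lines, paste(p$id, f2, p$chrom, p$r2_pos, p$r2_mapq,
                              paste0(rl, "M"), "=", p$start, 0L,
                              p$r2_seq, qual, sep = "\t"))
      pos <- c(pos, p$r2_pos)
    } else {
      f2 <- 1L + 128L + 4L + dup + (if (p$strand == "-") 32L else 0L)
      lines <- c(lines, paste(p$id, f2, p$chrom, p$start, 0L, "*", "=",
                              p$start, 0L, p$r2_seq, qual, sep = "\t"))
      pos <- c(pos, p$start)
    }
    ord_chrom <- c(ord_chrom, match(p$chrom, names(chrom_len)))
  }
  o <- order(ord_chrom, pos)
  writeLines(c(hdr, lines[o]), path)
}

#' Read a library's paired alignments from SAM/BAM
#'
#' Reads a coordinate-sorted, duplicate-marked alignment file (SAM is
#' converted to BAM on the fly) and assembles one row per read pair:
#' read-1 mapping coordinates and read-2 sequence as sequenced. Read
#' identity (first versus second of pair) is taken from the pairing
#' flags. Mapped reads on the minus strand have their stored sequence
#' reverse-complemented back to read orientation.
#'
#' @param path SAM or BAM file.
#' @param sample_id,subfamily library identity stamped on every pair
#'   (library identity comes from the run manifest, not from read
#'   names).
#' @return Pair table with the columns consumed by [filter_pairs()].
#' @export
read_alignments <- function(path, sample_id = "sample1",
                            subfamily = NA_character_) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1]]
  n <- length(res$qname)
  empty <- data.frame(id = character(), sample_id = character(),
                      subfamily = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), mapq = integer(),
                      r1_mapped = logical(), r2_seq = character(),
                      r2_mapped = logical(), r2_mapq = integer(),
                      is_duplicate = logical())
  if (n == 0L) return(empty)
  flag <- res$flag
  is_r1 <- bitwAnd(flag, 64L) > 0L
  is_r2 <- bitwAnd(flag, 128L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  rev <- bitwAnd(flag, 16L) > 0L
  dup <- bitwAnd(flag, 1024L) > 0L
  seqs <- as.character(res$seq)
  seqs[rev & !unmapped] <- as.character(
    Biostrings::reverseComplement(res$seq[rev & !unmapped]))
  width <- rep(NA_integer_, n)
  ok <- !unmapped & !is.na(res$cigar)
  width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[ok])
  qn <- res$qname
  i1 <- which(is_r1); i2 <- which(is_r2)
  m <- match(qn[i1], qn[i2])
  rows <- data.frame(
    id = qn[i1], sample_id = sample_id, subfamily = subfamily,
    chrom = as.character(res$rname[i1]),
    start = res$pos[i1],
    end = res$pos[i1] + width[i1] - 1L,
    strand = ifelse(rev[i1], "-", "+"),
    mapq = res$mapq[i1],
    r1_mapped = !unmapped[i1],
    r2_seq = ifelse(is.na(m), NA_character_, seqs[i2][m]),
    r2_mapped = ifelse(is.na(m), NA, !unmapped[i2][m]),
    r2_mapq = ifelse(is.na(m), NA_integer_, res$mapq[i2][m]),
    is_duplicate = dup[i1] | ifelse(is.na(m), FALSE, dup[i2][m]),
    stringsAsFactors = FALSE)
  rows[order(rows$chrom, rows$start), , drop = FALSE]
}

#' Read long-read alignments for validation
#'
#' Loads mapped long reads from BAM/SAM into the footprint+sequence
#' table consumed by [validate_with_long_reads()].
#'
#' @param path SAM or BAM file of long-read alignments.
#' @return Data frame with `chrom`, `start`, `end`, `seq`.
#' @export
read_long_reads <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  if (length(res$pos) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), seq = character()))
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  data.frame(chrom = as.character(res$rname), start = res$pos,
             end = res$pos + w - 1L, seq = as.character(res$seq),
             stringsAsFactors = FALSE)
}

#' Read BED intervals into the package's interval format
#'
#' Reads BED3+ (0-based half-open) into a 1-based closed data frame
#' suitable for [build_mask()] and friends.
#'
#' @param path BED file.
#' @return Data frame with `chrom`, `start`, `end` (1-based closed) and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4]])
  out
}
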