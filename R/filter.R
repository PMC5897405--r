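# Read-level QC mirroring mtDNA amplicon resequencing practice: discard
# reads missing a mate, with mean base quality < 30, or shorter than 30 bp;
# then collapse PCR duplicates by coordinate + alignment structure.

.mean_read_quality <- function(qual) {
  vapply(qual, function(s) mean(utf8ToInt(s)) - 33, numeric(1L),
         USE.NAMES = FALSE)
}

.sum_read_quality <- function(qual) {
  vapply(qual, function(s) sum(utf8ToInt(s) - 33L), numeric(1L),
         USE.NAMES = FALSE)
}

#' Quality-filter aligned reads
#'
#' Retains a read iff it has a complete pair (unless `require_pair = FALSE`),
#' its mean base quality is at least `min_mean_quality`, and it is at least
#' `min_length` bases long. The inequalities are strict discards: a read at
#' exactly the boundary (mean quality 30, length 30) is retained.
#'
#' @param reads An `aligned_reads` table.
#' @param min_mean_quality Minimum mean Phred quality (default 30).
#' @param min_length Minimum read length in bases (default 30).
#' @param require_pair Discard reads whose mate is missing (default `TRUE`).
#' @return A list with `reads` (the retained rows) and `report`, a data
#'   frame counting, per criterion, how many input reads failed it
#'   (a read failing several criteria is counted under each).
#' @export
filter_reads <- function(reads, min_mean_quality = 30, min_length = 30,
                         require_pair = TRUE) {
  if (nrow(reads) == 0L) {
    report <- data.frame(criterion = c("missing_mate", "mean_quality", "length"),
                         n_removed = c(0L, 0L, 0L))
    return(list(reads = reads, report = report))
  }
  len <- nchar(reads$seq)
  mq <- .mean_read_quality(reads$qual)
  fail_pair <- if (require_pair) !reads$is_paired_complete else rep(FALSE, nrow(reads))
  fail_qual <- mq < min_mean_quality
  fail_len <- len < min_length
  keep <- !(fail_pair | fail_qual | fail_len)
  report <- data.frame(
    criterion = c("missing_mate", "mean_quality", "length"),
    n_removed = c(sum(fail_pair), sum(fail_qual), sum(fail_len))
  )
  list(reads = reads[keep, , drop = FALSE], report = report)
}

#' Mark PCR duplicates
#'
#' Reads sharing reference name, leftmost position, CIGAR string, strand
#' and mate position (fragment identity) are treated as PCR copies of one
#' fragment; the copy with the highest summed base quality keeps
#' `is_duplicate = FALSE`, the rest are marked `TRUE`. Keying on the
#' fragment (read plus mate coordinates, as external duplicate markers do)
#' rather than the read alone matters at amplicon depth, where many
#' distinct fragments share a read start. Downstream operations skip marked
#' reads.
#'
#' @param reads An `aligned_reads` table.
#' @return The same table with `is_duplicate` set.
#' @export
mark_duplicates <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  strand <- ifelse(bitwAnd(reads$flag, .FLAG_REVERSE) > 0L, "-", "+")
  key <- paste(reads$rname, reads$pos, reads$cigar, strand, reads$pnext,
               sep = "\r")
  sq <- .sum_read_quality(reads$qual)
  ord <- order(key, -sq)
  dup <- duplicated(key[ord])
  is_dup <- logical(nrow(reads))
  is_dup[ord] <- dup
  reads$is_duplicate <- is_dup
  reads
}

#' Drop marked duplicates
#'
#' @param reads An `aligned_reads` table with `is_duplicate` set.
#' @return The non-duplicate rows.
#' @export
drop_duplicates <- function(reads) reads[!reads$is_duplicate, , drop = FALSE]
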