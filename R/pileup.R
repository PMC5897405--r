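# Single-position pileup with a base-quality floor, and the allele-frequency
# classifier: alternate frequency > 90% is called homoplasmic, 40-90%
# (inclusive) heteroplasmic, below 40% low-level.

#' Per-base pileup counts and frequencies at one reference position
#'
#' For every non-duplicate read covering `position`, walks the CIGAR to find
#' the query base aligned there. Bases with Phred quality at or above
#' `min_base_quality` are counted; lower-quality bases, deletions spanning
#' the position and insertions immediately before it are tallied separately
#' as depth loss.
#'
#' @param reads An `aligned_reads` table.
#' @param position 1-based reference coordinate.
#' @param min_base_quality Minimum base quality to count (default 30).
#' @return A list with `position`, `counts` (named by base), `frequencies`
#'   (over counted bases; empty when nothing qualifies), `depth_used`,
#'   `n_below_quality`, `n_deletion`, `n_insertion`.
#' @export
pileup_frequencies <- function(reads, position, min_base_quality = 30) {
  reads <- reads[!reads$is_duplicate, , drop = FALSE]
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  n_below <- 0L; n_del <- 0L; n_ins <- 0L
  for (i in seq_len(nrow(reads))) {
    read <- reads[i, ]
    span <- reference_span(read)
    if (position < span[1L] || position >= span[2L]) next
    ops <- parse_cigar(read$cigar)
    refpos <- read$pos; qpos <- 1L
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op == "S" ) {
        qpos <- qpos + len
      } else if (op == "H") {
      } else if (op == "I") {
        if (refpos == position) n_ins <- n_ins + 1L
        qpos <- qpos + len
      } else if (op == "D") {
        if (position >= refpos && position < refpos + len) {
          n_del <- n_del + 1L
          break
        }
        refpos <- refpos + len
      } else { # M/=/X
        if (position >= refpos && position < refpos + len) {
          qi <- qpos + (position - refpos)
          base <- toupper(substr(read$seq, qi, qi))
          q <- utf8ToInt(substr(read$qual, qi, qi)) - 33L
          if (q >= min_base_quality) {
            if (!base %in% names(counts)) base <- "N"
            counts[base] <- counts[base] + 1L
          } else {
            n_below <- n_below + 1L
          }
          break
        }
        refpos <- refpos + len
        qpos <- qpos + len
      }
    }
  }
  counts <- counts[counts > 0L | names(counts) %in% c("A", "C", "G", "T")]
  depth <- sum(counts)
  freqs <- if (depth > 0L) counts / depth else stats::setNames(numeric(0L), character(0L))
  list(position = position, counts = counts, frequencies = freqs,
       depth_used = depth, n_below_quality = n_below,
       n_deletion = n_del, n_insertion = n_ins)
}

#' Classify a site from its alternate-allele frequency
#'
#' Applies the fixed heteroplasmy bands: alternate frequency strictly above
#' 0.90 is `"homoplasmic"`, between 0.40 and 0.90 inclusive is
#' `"heteroplasmic"`, and below 0.40 is `"low_level"`. Vectorised.
#'
#' @param alt_frequency Numeric in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' classify_site(c(0.10, 0.65, 0.95))
#' @export
classify_site <- function(alt_frequency) {
  if (any(is.na(alt_frequency)) ||
      any(alt_frequency < 0) || any(alt_frequency > 1))
    stop("alt_frequency must lie in [0, 1]")
  ifelse(alt_frequency > 0.90, "homoplasmic",
         ifelse(alt_frequency >= 0.40, "heteroplasmic", "low_level"))
}
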