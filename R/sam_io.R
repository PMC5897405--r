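# Reader/writer for the minimal SAM text dialect produced by the simulator
# and consumed by the heteroplasmy caller. Qualities are Phred+33 throughout.

.FLAG_PAIRED       <- 0x1L
.FLAG_UNMAPPED     <- 0x4L
.FLAG_MATE_UNMAP   <- 0x8L
.FLAG_REVERSE      <- 0x10L
.FLAG_SECONDARY    <- 0x100L
.FLAG_DUPLICATE    <- 0x400L
.FLAG_SUPPLEMENT   <- 0x800L

#' Parse SAM text into a reads table
#'
#' Reads the mapped records of a SAM file (or character vector of lines) into
#' a data frame, one row per mapped primary record. Unmapped records, records
#' without a CIGAR (`*`), and secondary/supplementary alignments are skipped
#' and counted in the `skipped` attribute. Base qualities stay encoded as
#' Phred+33 strings; decode with [phred33_to_int()].
#'
#' @param input Path to a SAM file, or a character vector of SAM lines.
#' @return A data frame of class `aligned_reads` with columns `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual`, `is_paired_complete`, `is_duplicate`, plus attributes
#'   `skipped`
#'   (named counts of skipped records) and `header` (the `@` lines).
#' @details A record whose CIGAR query footprint disagrees with the length
#'   of its bases or qualities, or with a non-numeric position or too few
#'   fields, is rejected with an error naming the offending line number.
#' @export
parse_sam <- function(input) {
  lines <- if (length(input) == 1L && !grepl("[\t\n]", input) &&
               file.exists(input)) readLines(input) else input
  is_header <- startsWith(lines, "@")
  header <- lines[is_header]
  body_idx <- which(!is_header & nzchar(lines))
  skipped <- c(unmapped = 0L, missing_cigar = 0L, secondary = 0L)

  recs <- vector("list", length(body_idx))
  keep <- logical(length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("malformed SAM record at line ", ln, ": expected >= 11 fields, got ",
           length(f))
    flag <- suppressWarnings(as.integer(f[2L]))
    pos  <- suppressWarnings(as.integer(f[4L]))
    mapq <- suppressWarnings(as.integer(f[5L]))
    if (is.na(flag) || is.na(pos))
      stop("malformed SAM record at line ", ln, ": non-numeric flag/position")
    if (bitwAnd(flag, .FLAG_UNMAPPED) > 0L) {
      skipped["unmapped"] <- skipped["unmapped"] + 1L
      next
    }
    if (bitwAnd(flag, .FLAG_SECONDARY) > 0L ||
        bitwAnd(flag, .FLAG_SUPPLEMENT) > 0L) {
      skipped["secondary"] <- skipped["secondary"] + 1L
      next
    }
    if (f[6L] == "*") {
      skipped["missing_cigar"] <- skipped["missing_cigar"] + 1L
      next
    }
    if (pos < 1L)
      stop("malformed SAM record at line ", ln, ": position < 1")
    seq <- f[10L]; qual <- f[11L]
    qlen <- cigar_query_length(f[6L])
    if (seq == "*" || nchar(seq) != qlen || nchar(qual) != qlen)
      stop("malformed SAM record at line ", ln,
           ": CIGAR query length ", qlen, " disagrees with SEQ/QUAL")
    pnext <- suppressWarnings(as.integer(f[8L]))
    tlen <- suppressWarnings(as.integer(f[9L]))
    if (is.na(pnext) || is.na(tlen))
      stop("malformed SAM record at line ", ln, ": non-numeric PNEXT/TLEN")
    keep[i] <- TRUE
    recs[[i]] <- list(qname = f[1L], flag = flag, rname = f[3L], pos = pos,
                      mapq = mapq, cigar = f[6L], rnext = f[7L],
                      pnext = pnext, tlen = tlen, seq = seq, qual = qual)
  }
  recs <- recs[keep]
  reads <- if (length(recs)) {
    data.frame(
      qname = vapply(recs, `[[`, "", "qname"),
      flag  = vapply(recs, `[[`, 0L, "flag"),
      rname = vapply(recs, `[[`, "", "rname"),
      pos   = vapply(recs, `[[`, 0L, "pos"),
      mapq  = vapply(recs, `[[`, 0L, "mapq"),
      cigar = vapply(recs, `[[`, "", "cigar"),
      rnext = vapply(recs, `[[`, "", "rnext"),
      pnext = vapply(recs, `[[`, 0L, "pnext"),
      tlen  = vapply(recs, `[[`, 0L, "tlen"),
      seq   = vapply(recs, `[[`, "", "seq"),
      qual  = vapply(recs, `[[`, "", "qual"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(qname = character(), flag = integer(), rname = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               rnext = character(), pnext = integer(), tlen = integer(),
               seq = character(), qual = character(),
               stringsAsFactors = FALSE)
  }
  reads$is_paired_complete <- bitwAnd(reads$flag, .FLAG_PAIRED) > 0L &
    bitwAnd(reads$flag, .FLAG_MATE_UNMAP) == 0L
  reads$is_duplicate <- bitwAnd(reads$flag, .FLAG_DUPLICATE) > 0L
  structure(reads, skipped = skipped, header = header,
            class = c("aligned_reads", "data.frame"))
}

#' Serialise a reads table to SAM text
#'
#' Writes the reads of an `aligned_reads` table back to SAM lines (or a
#' file). Round-trips with [parse_sam()]: every field survives exactly.
#' Reads whose CIGAR query footprint disagrees with their bases/qualities
#' are refused.
#'
#' @param reads A reads table as returned by [parse_sam()] or
#'   [simulate_polyA_reads()].
#' @param path Optional output file; if `NULL` the lines are returned.
#' @param header Optional character vector of `@` header lines. If missing,
#'   a minimal `@HD`/`@SQ` header is generated from the reads.
#' @param ref_length Reference length for the generated `@SQ` line.
#' @return The SAM lines, invisibly when `path` is given.
#' @export
write_sam <- function(reads, path = NULL, header = NULL, ref_length = NULL) {
  if (nrow(reads)) {
    qlen <- vapply(reads$cigar, cigar_query_length, integer(1L),
                   USE.NAMES = FALSE)
    bad <- which(nchar(reads$seq) != qlen | nchar(reads$qual) != qlen)
    if (length(bad))
      stop("refusing to serialise read(s) violating the length invariant: ",
           paste(utils::head(reads$qname[bad], 5L), collapse = ", "))
  }
  if (is.null(header)) {
    rnames <- unique(reads$rname)
    if (is.null(ref_length))
      ref_length <- if (nrow(reads)) max(.reference_ends(reads)) + 1000L else 1000L
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", rnames, as.integer(ref_length)))
  }
  flag <- reads$flag
  # keep derived columns consistent with the flag field on output
  flag <- ifelse(reads$is_duplicate, bitwOr(flag, .FLAG_DUPLICATE),
                 bitwAnd(flag, bitwNot(.FLAG_DUPLICATE)))
  body <- if (nrow(reads)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            reads$qname, flag, reads$rname, reads$pos, reads$mapq,
            reads$cigar, reads$rnext, reads$pnext, reads$tlen,
            reads$seq, reads$qual)
  } else character()
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Decode and encode Phred+33 quality strings
#'
#' @param qual A quality string (one read).
#' @return `phred33_to_int()`: integer Phred scores; `int_to_phred33()`:
#'   the encoded string.
#' @export
phred33_to_int <- function(qual) utf8ToInt(qual) - 33L

#' @rdname phred33_to_int
#' @param q Integer Phred scores.
#' @export
int_to_phred33 <- function(q) intToUtf8(q + 33L)
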