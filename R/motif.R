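# The repeat-length caller: reconstruct the read sequence over a reference
# window by walking the CIGAR, then measure the anchored homopolymer run in
# the reconstructed text. Because the run is read off the reconstruction,
# the count is invariant to where the aligner placed the indel inside the
# run (left- or right-aligned CIGARs give the same text).

#' Reconstruct a read's sequence over a reference window
#'
#' Walks the CIGAR operation by operation and emits the query bases aligned
#' over the half-open reference window `[window[1], window[2])`: `M`/`=`/`X`
#' emit their query bases, `D` emits nothing, and `I` emits its query bases
#' when the insertion point lies inside the window (left edge inclusive,
#' right edge exclusive -- so an insertion exactly at the window start is
#' attributed to the window). Soft clips are excluded.
#'
#' @param read One read (row of an `aligned_reads` table, or a list with
#'   `pos`, `cigar`, `seq`, `qual`).
#' @param window Integer `c(start, end)`, half-open, 1-based.
#' @param partial If `FALSE` (default) a read whose reference span does not
#'   contain the whole window yields `NULL` (the "not spanning" signal,
#'   not an error). If `TRUE` the window is clipped to the read's span and
#'   the overlapping part is reconstructed.
#' @param ops Pre-parsed CIGAR operations (internal optimisation; defaults
#'   to parsing `read$cigar`).
#' @return `NULL`, or a list with `seq` (character string), `qual` (integer
#'   Phred scores, same length) and `complete` (did the read cover the full
#'   requested window).
#' @export
reconstruct_window <- function(read, window, partial = FALSE,
                               ops = parse_cigar(read$cigar)) {
  w <- sum(ops$len[ops$op %in% .ref_ops])
  if (w == 0L) stop("no reference footprint (CIGAR has only S/H/I operations)")
  span <- c(read$pos, read$pos + w)
  wlo <- window[1L]; whi <- window[2L]
  complete <- span[1L] <= wlo && span[2L] >= whi
  if (!complete) {
    if (!partial) return(NULL)
    wlo <- max(wlo, span[1L]); whi <- min(whi, span[2L])
    if (wlo >= whi) return(NULL)
  }
  q <- utf8ToInt(read$qual) - 33L
  refpos <- read$pos; qpos <- 1L
  pieces <- character(0L)
  qidx <- integer(0L)
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op == "S") {
      qpos <- qpos + len
    } else if (op == "H") {
      # consumes neither bases nor reference
    } else if (op == "I") {
      if (refpos >= wlo && refpos < whi) {
        pieces <- c(pieces, substr(read$seq, qpos, qpos + len - 1L))
        qidx <- c(qidx, qpos:(qpos + len - 1L))
      }
      qpos <- qpos + len
    } else if (op == "D") {
      refpos <- refpos + len
    } else { # M, =, X
      ov_lo <- max(refpos, wlo); ov_hi <- min(refpos + len, whi)
      if (ov_lo < ov_hi) {
        a <- qpos + (ov_lo - refpos)
        b <- a + (ov_hi - ov_lo) - 1L
        pieces <- c(pieces, substr(read$seq, a, b))
        qidx <- c(qidx, a:b)
      }
      refpos <- refpos + len
      qpos <- qpos + len
    }
    if (refpos >= whi && qpos > nchar(read$seq)) break
  }
  list(seq = paste0(pieces, collapse = ""), qual = q[qidx],
       complete = complete)
}

#' Extract a homopolymer motif observation from one read
#'
#' Reconstructs the window from one base before the anchor through
#' `reference_run_length + slack` bases past the run, finds the first
#' maximal run of the anchor base, and counts the maximal run of the repeat
#' base immediately following it. The observation is spanning only when a
#' base different from the repeat base (the terminator) is visible after the
#' run -- a read ending inside the run cannot distinguish an 11A from a 12A
#' molecule and is censored rather than truncated. The mean Phred quality
#' over the motif bases (anchor run plus repeat run) must be at least
#' `min_motif_quality` (strictly below is discarded).
#'
#' @param read One read.
#' @param site A [motif_site()].
#' @param min_motif_quality Minimum mean motif quality (default 20).
#' @param slack Reference bases past the run searched for the terminator
#'   (default 6).
#' @return A list with `read_name`, `run_length` (NA when rejected),
#'   `mean_motif_quality`, `spanning`, `accepted` and `reason` (one of
#'   `"ok"`, `"not_spanning"`, `"anchor_not_found"`, `"low_quality"`).
#' @export
extract_motif <- function(read, site, min_motif_quality = 20, slack = 6L) {
  run_start <- site$anchor_position + 1L
  wlo <- site$anchor_position - 1L
  whi <- run_start + site$reference_run_length + as.integer(slack)
  rej <- function(reason, spanning = FALSE, q = NA_real_) {
    list(read_name = read$qname, run_length = NA_integer_,
         mean_motif_quality = q, spanning = spanning, accepted = FALSE,
         reason = reason)
  }
  ops <- parse_cigar(read$cigar)
  span <- c(read$pos, read$pos + sum(ops$len[ops$op %in% .ref_ops]))
  if (span[1L] > wlo || span[2L] <= run_start)
    return(rej("not_spanning"))
  rec <- reconstruct_window(read, c(wlo, whi), partial = TRUE, ops = ops)
  if (is.null(rec) || !nzchar(rec$seq))
    return(rej("not_spanning"))
  text <- rec$seq
  m <- regexpr(paste0(site$anchor_base, "+"), text, fixed = FALSE)
  if (m[1L] == -1L)
    return(rej("anchor_not_found"))
  a_start <- m[1L] + attr(m, "match.length")
  rest <- substring(text, a_start)
  rl <- attr(regexpr(paste0("^", site$repeat_base, "*"), rest), "match.length")
  if (nchar(rest) <= rl)  # run reaches the end of the visible text
    return(rej("not_spanning"))
  motif_q <- rec$qual[m[1L]:(a_start + rl - 1L)]
  mq <- mean(motif_q)
  if (mq < min_motif_quality)
    return(rej("low_quality", spanning = TRUE, q = mq))
  list(read_name = read$qname, run_length = as.integer(rl),
       mean_motif_quality = mq, spanning = TRUE, accepted = TRUE,
       reason = "ok")
}

#' Extract motif observations for a whole reads table
#'
#' Applies [extract_motif()] to every non-duplicate read and returns one row
#' per read. Duplicate-flagged reads are skipped.
#'
#' @inheritParams extract_motif
#' @param reads An `aligned_reads` table.
#' @return A data frame with columns `read_name`, `run_length`,
#'   `mean_motif_quality`, `spanning`, `accepted`, `reason`.
#' @export
extract_motifs <- function(reads, site, min_motif_quality = 20, slack = 6L) {
  reads <- reads[!reads$is_duplicate, , drop = FALSE]
  n <- nrow(reads)
  run_length <- integer(n); meanq <- numeric(n)
  spanning <- logical(n); accepted <- logical(n); reason <- character(n)
  qn <- reads$qname; po <- reads$pos; cg <- reads$cigar
  sq <- reads$seq; ql <- reads$qual
  for (i in seq_len(n)) {
    ob <- extract_motif(list(qname = qn[i], pos = po[i], cigar = cg[i],
                             seq = sq[i], qual = ql[i]),
                        site, min_motif_quality, slack)
    run_length[i] <- ob$run_length
    meanq[i] <- ob$mean_motif_quality
    spanning[i] <- ob$spanning
    accepted[i] <- ob$accepted
    reason[i] <- ob$reason
  }
  data.frame(read_name = reads$qname, run_length = run_length,
             mean_motif_quality = meanq, spanning = spanning,
             accepted = accepted, reason = reason,
             stringsAsFactors = FALSE)
}

#' Tally observed repeat lengths into a spectrum
#'
#' Counts accepted motif observations by run length and normalises to
#' fractions. With zero accepted observations the spectrum has `total = 0`
#' and an empty fractions vector.
#'
#' @param observations A data frame from [extract_motifs()] (rows with
#'   `accepted = FALSE` are ignored), or an integer vector of run lengths.
#' @param site The [motif_site()] the observations came from.
#' @return A list of class `length_spectrum` with `site`, `counts` (named
#'   integer vector, names are run lengths), `total` and `fractions`.
#' @export
count_spectrum <- function(observations, site) {
  lens <- if (is.data.frame(observations)) {
    observations$run_length[observations$accepted]
  } else {
    as.integer(observations)
  }
  lens <- lens[!is.na(lens)]
  counts <- table(lens)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  fractions <- if (total > 0L) counts / total else stats::setNames(numeric(0L), character(0L))
  structure(list(site = site, counts = counts, total = total,
                 fractions = fractions),
            class = "length_spectrum")
}

#' @export
print.length_spectrum <- function(x, ...) {
  cat(sprintf("<length_spectrum> %s: %d observations\n", x$site$name, x$total))
  if (x$total > 0L) print(round(x$fractions, 4L))
  invisible(x)
}

#' Per-length heteroplasmy fractions and aggregates
#'
#' Summarises a length spectrum into the per-sample heteroplasmy statistics:
#' the fraction at each observed run length, the fraction at the reference
#' length, the fraction one unit above it (the "12A" statistic at OriL), and
#' the aggregate fraction of runs longer than the reference.
#'
#' @param spectrum A `length_spectrum` with `total > 0`.
#' @return A list with `per_length` (data frame: `run_length`, `count`,
#'   `fraction`), `ref_fraction`, `plus_one_fraction` and
#'   `gt_ref_fraction`.
#' @export
heteroplasmy_metrics <- function(spectrum) {
  if (spectrum$total == 0L)
    stop("empty spectrum: no accepted observations")
  L <- as.integer(names(spectrum$counts))
  per_length <- data.frame(run_length = L,
                           count = as.integer(spectrum$counts),
                           fraction = as.numeric(spectrum$fractions))
  ref <- spectrum$site$reference_run_length
  frac_at <- function(l) {
    i <- match(l, L)
    if (is.na(i)) 0 else per_length$fraction[i]
  }
  list(per_length = per_length,
       ref_fraction = frac_at(ref),
       plus_one_fraction = frac_at(ref + 1L),
       gt_ref_fraction = sum(per_length$fraction[L > ref]))
}
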