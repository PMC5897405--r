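# Independent brute-force oracles and fixture builders. The oracles share no
# code with the package implementation: CIGARs are exploded character by
# character and windows are assembled position by position, then scanned
# with plain while-loops.

qual_str <- function(scores) intToUtf8(scores + 33L)

make_read <- function(pos, cigar, seq = NULL, qual = NULL, flag = 99L,
                      qname = "r1", rname = "chrM") {
  qlen <- cigar_query_length(cigar)
  if (is.null(seq))
    seq <- paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE),
                 collapse = "")
  if (is.null(qual)) qual <- strrep("D", qlen)  # Phred 35 throughout
  df <- data.frame(qname = qname, flag = flag, rname = rname,
                   pos = as.integer(pos), mapq = 60L, cigar = cigar,
                   rnext = "=", pnext = as.integer(pos + 200L), tlen = 350L,
                   seq = seq, qual = qual, stringsAsFactors = FALSE)
  df$is_paired_complete <- bitwAnd(df$flag, 0x1L) > 0L &
    bitwAnd(df$flag, 0x8L) == 0L
  df$is_duplicate <- FALSE
  class(df) <- c("aligned_reads", "data.frame")
  df
}

# Explode a CIGAR string by scanning characters (no regex).
explode_cigar <- function(cigar) {
  num <- ""
  out <- list()
  for (ch in strsplit(cigar, "")[[1L]]) {
    if (ch >= "0" && ch <= "9") {
      num <- paste0(num, ch)
    } else {
      out[[length(out) + 1L]] <- list(op = ch, len = as.integer(num))
      num <- ""
    }
  }
  out
}

# Brute-force reference span: advance a counter op by op.
oracle_reference_span <- function(pos, cigar) {
  p <- pos
  for (o in explode_cigar(cigar)) {
    if (o$op %in% c("M", "D", "=", "X")) p <- p + o$len
  }
  if (p == pos) stop("no reference footprint")
  c(pos, p)
}

# Brute-force motif extraction: build a per-position map of aligned bases
# and insertions, assemble the window text linearly, scan with while-loops.
oracle_extract_motif <- function(read, site, min_motif_quality = 20,
                                 slack = 6L) {
  sv <- strsplit(read$seq, "")[[1L]]
  qv <- utf8ToInt(read$qual) - 33L
  base_at <- list(); qual_at <- list(); ins_at <- list(); insq_at <- list()
  refpos <- read$pos; qpos <- 1L
  for (o in explode_cigar(read$cigar)) {
    if (o$op == "S") {
      qpos <- qpos + o$len
    } else if (o$op == "H") {
    } else if (o$op == "I") {
      key <- as.character(refpos)
      ins_at[[key]] <- c(ins_at[[key]], sv[qpos:(qpos + o$len - 1L)])
      insq_at[[key]] <- c(insq_at[[key]], qv[qpos:(qpos + o$len - 1L)])
      qpos <- qpos + o$len
    } else if (o$op == "D") {
      refpos <- refpos + o$len
    } else {
      for (j in seq_len(o$len)) {
        key <- as.character(refpos)
        base_at[[key]] <- sv[qpos]
        qual_at[[key]] <- qv[qpos]
        refpos <- refpos + 1L
        qpos <- qpos + 1L
      }
    }
  }
  span_lo <- read$pos; span_hi <- refpos
  run_start <- site$anchor_position + 1L
  wlo <- site$anchor_position - 1L
  whi <- run_start + site$reference_run_length + slack
  not_spanning <- list(run_length = NA_integer_, accepted = FALSE,
                       spanning = FALSE, reason = "not_spanning")
  if (span_lo > wlo || span_hi <= run_start) return(not_spanning)
  hi <- min(whi, span_hi)
  text <- character(0L); tq <- numeric(0L)
  for (p in wlo:(hi - 1L)) {
    key <- as.character(p)
    if (!is.null(ins_at[[key]])) {
      text <- c(text, ins_at[[key]]); tq <- c(tq, insq_at[[key]])
    }
    if (!is.null(base_at[[key]])) {
      text <- c(text, base_at[[key]]); tq <- c(tq, qual_at[[key]])
    }
  }
  n <- length(text)
  if (n == 0L) return(not_spanning)
  i <- 1L
  while (i <= n && text[i] != site$anchor_base) i <- i + 1L
  if (i > n)
    return(list(run_length = NA_integer_, accepted = FALSE,
                spanning = FALSE, reason = "anchor_not_found"))
  a0 <- i
  while (i <= n && text[i] == site$anchor_base) i <- i + 1L
  r0 <- i; rl <- 0L
  while (i <= n && text[i] == site$repeat_base) { rl <- rl + 1L; i <- i + 1L }
  if (i > n) return(not_spanning)
  mq <- mean(tq[a0:(r0 + rl - 1L)])
  if (mq < min_motif_quality)
    return(list(run_length = NA_integer_, accepted = FALSE, spanning = TRUE,
                reason = "low_quality"))
  list(run_length = rl, accepted = TRUE, spanning = TRUE, reason = "ok",
       mean_motif_quality = mq)
}

# A random valid CIGAR with >= 1 reference-consuming op: optional leading
# clip, then alternating M with occasional I/D, optional trailing clip.
random_cigar <- function() {
  mid_n <- sample(1:4, 1L)
  ops <- c()
  for (k in seq_len(mid_n)) {
    ops <- c(ops, paste0(sample(5:60, 1L), "M"))
    if (k < mid_n) {
      op <- sample(c("I", "D"), 1L)
      ops <- c(ops, paste0(sample(1:4, 1L), op))
    }
  }
  if (runif(1L) < 0.3) ops <- c(paste0(sample(1:10, 1L), "S"), ops)
  if (runif(1L) < 0.3) ops <- c(ops, paste0(sample(1:10, 1L), "S"))
  paste(ops, collapse = "")
}

# A read whose sequence matches the OriL reference exactly over its span.
reference_read <- function(ref, pos, len = 150L, qual = NULL) {
  i <- pos - ref$start + 1L
  make_read(pos, paste0(len, "M"),
            seq = substr(ref$seq, i, i + len - 1L), qual = qual)
}
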