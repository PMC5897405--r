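# CIGAR arithmetic for the minimal alignment dialect consumed by the caller.
# Coordinates are 1-based inclusive positions; spans are half-open [start, end).

.cigar_ops   <- c("M", "I", "D", "S", "H", "=", "X")
.query_ops   <- c("M", "I", "S", "=", "X")
.ref_ops     <- c("M", "D", "=", "X")

#' Parse a CIGAR string into operations
#'
#' Splits a CIGAR string such as `"12M1I27M"` into its ordered operations.
#' Supported operations are `M`, `I`, `D`, `S`, `H`, `=` and `X`; `N` and `P`
#' do not occur in amplicon data and are rejected.
#'
#' @param cigar A single CIGAR string.
#' @return A data frame with columns `op` (character) and `len` (integer),
#'   one row per operation in order.
#' @examples
#' parse_cigar("12M1I27M")
#' @export
parse_cigar <- function(cigar) {
  if (!is.character(cigar) || length(cigar) != 1L)
    stop("cigar must be a single string")
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*")
    stop("CIGAR is absent ('*')")
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1L]]
  nc <- nchar(toks)
  if (sum(nc) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  op <- substr(toks, nc, nc)
  bad <- setdiff(op, .cigar_ops)
  if (length(bad))
    stop("unsupported CIGAR operation(s): ", paste(bad, collapse = ", "))
  len <- as.integer(substr(toks, 1L, nc - 1L))
  if (any(len < 1L))
    stop("CIGAR operation length must be >= 1: ", cigar)
  structure(list(op = op, len = len), class = "data.frame",
            row.names = seq_along(op))
}

#' Query and reference footprints of a CIGAR
#'
#' `cigar_query_length()` sums the lengths of query-consuming operations
#' (`M`, `I`, `S`, `=`, `X`); it must equal the length of the read's bases
#' and qualities. `cigar_reference_length()` sums reference-consuming
#' operations (`M`, `D`, `=`, `X`).
#'
#' @param ops A parsed CIGAR from [parse_cigar()], or a CIGAR string.
#' @return An integer length.
#' @export
cigar_query_length <- function(ops) {
  if (is.character(ops)) ops <- parse_cigar(ops)
  sum(ops$len[ops$op %in% .query_ops])
}

#' @rdname cigar_query_length
#' @export
cigar_reference_length <- function(ops) {
  if (is.character(ops)) ops <- parse_cigar(ops)
  sum(ops$len[ops$op %in% .ref_ops])
}

#' Reference interval covered by an aligned read
#'
#' Returns the half-open 1-based reference interval
#' `[position, position + reference footprint)` of a read. Soft and hard
#' clips and insertions consume no reference, so a read at position 100 with
#' CIGAR `"10S30M"` spans `[100, 130)`.
#'
#' @param read A single read: either one row of an [parse_sam()] data frame
#'   or a list with elements `pos` and `cigar`.
#' @return Integer vector `c(start, end)`, half-open.
#' @export
reference_span <- function(read) {
  ops <- parse_cigar(read$cigar)
  w <- cigar_reference_length(ops)
  if (w == 0L)
    stop("no reference footprint (CIGAR has only S/H/I operations)")
  c(read$pos, read$pos + w)
}

# Vectorised reference end positions for a reads table (internal).
.reference_ends <- function(reads) {
  reads$pos + vapply(reads$cigar, cigar_reference_length, integer(1L),
                     USE.NAMES = FALSE)
}
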