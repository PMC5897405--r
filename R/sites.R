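# Anchored homopolymer site definitions. A site is an anchor base whose run
# starts at a fixed reference coordinate, immediately followed by the
# repeated base; the observable of interest is the length of that run.

#' Define an anchored homopolymer site
#'
#' A motif site is an anchor base (one or more copies tolerated) immediately
#' followed by a homopolymer run of a different base. For mouse mtDNA the
#' two loci of interest are the OriL poly-A loop (anchor G at nt 5171,
#' adenine run from nt 5172, reference length 11) and the mt-Tr poly-A
#' (anchor T at nt 9820, adenine run from nt 9821, reference length 8).
#'
#' @param name Site label used in outputs.
#' @param anchor_base Single anchor nucleotide (must differ from
#'   `repeat_base`).
#' @param anchor_position 1-based reference coordinate of the anchor.
#' @param repeat_base The repeated nucleotide.
#' @param reference_run_length Reference length of the run (>= 1).
#' @return A list of class `motif_site`.
#' @export
motif_site <- function(name, anchor_base, anchor_position, repeat_base,
                       reference_run_length) {
  anchor_base <- toupper(anchor_base)
  repeat_base <- toupper(repeat_base)
  stopifnot(nchar(anchor_base) == 1L, nchar(repeat_base) == 1L)
  if (anchor_base == repeat_base)
    stop("anchor base must differ from the repeated base")
  if (reference_run_length < 1L)
    stop("reference_run_length must be >= 1")
  if (anchor_position < 1L)
    stop("anchor_position must be >= 1")
  structure(list(name = name,
                 anchor_base = anchor_base,
                 anchor_position = as.integer(anchor_position),
                 repeat_base = repeat_base,
                 reference_run_length = as.integer(reference_run_length)),
            class = "motif_site")
}

#' Shipped site definitions
#'
#' `oril_site()`: the OriL poly-A loop of mouse mtDNA (G anchor at nt 5171,
#' 11-adenine reference run from nt 5172). `mttr_site()`: the mt-Tr
#' (tRNA-arginine) poly-A (T anchor at nt 9820, 8-adenine reference run from
#' nt 9821).
#'
#' @return A `motif_site`.
#' @export
oril_site <- function() motif_site("OriL-5172", "G", 5171L, "A", 11L)

#' @rdname oril_site
#' @export
mttr_site <- function() motif_site("mt-Tr-9821", "T", 9820L, "A", 8L)

#' @export
print.motif_site <- function(x, ...) {
  cat(sprintf("<motif_site> %s: %s anchor at %d, %s-run of %d from %d\n",
              x$name, x$anchor_base, x$anchor_position, x$repeat_base,
              x$reference_run_length, x$anchor_position + 1L))
  invisible(x)
}
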