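#' Specification of the canonical IS element
#'
#' Describes the anatomy of a canonical IS5-family-like element used by the
#' forward simulator: a `total_length` bp element bounded by asymmetric
#' terminal inverted repeats (TIRs) of `tir_length` bp that are identical
#' except for a single A/T difference at nucleotide position (np)
#' `mismatch_np`, a transposase open reading frame on the top strand, and
#' sigma-70 promoter hexamers (the -35 box inside the left TIR, the -10 box
#' just downstream of it, with a 17-bp spacer under the defaults).
#'
#' Coordinates follow the "np" convention: 1-based positions counted from
#' the element's outer end (np 1 is the first nucleotide of the left TIR).
#' The "inward read" of a TIR is its sequence read from the element's outer
#' edge toward the interior: top strand on the left end, bottom strand on
#' the right end, so the element's top strand starts with
#' `left_tir_inward` and ends with `revcomp(right_tir_inward)`.
#'
#' By default `right_tir_inward` is derived from `left_tir_inward` by
#' complementing the base at `mismatch_np` (A at np 17 on the left, T on the
#' right), reproducing the diagnostic asymmetry that makes post-inversion
#' TIR configurations mechanistically informative.
#'
#' The default ORF occupies np 34..891 (858 bp, 286 codons): it starts
#' immediately after the -10 box so that the promoter hexamers are not
#' constrained by coding requirements, and ends two filler positions before
#' the right TIR.
#'
#' @param tir_length TIR length in bp.
#' @param mismatch_np 1-based position of the single left/right TIR
#'   difference, counted from the element's outer end.
#' @param left_tir_inward Inward read of the left TIR (length `tir_length`).
#' @param right_tir_inward Inward read of the right TIR; defaults to
#'   `left_tir_inward` with the base at `mismatch_np` complemented.
#' @param orf_length Transposase ORF length in bp (start codon through stop
#'   codon, inclusive); must be divisible by 3.
#' @param minus35_np Integer vector of length 2: 1-based inclusive np
#'   interval of the -35 hexamer.
#' @param minus35_seq The -35 hexamer sequence.
#' @param minus10_np Integer vector of length 2: np interval of the -10
#'   hexamer.
#' @param minus10_seq The -10 hexamer sequence.
#' @param total_length Total element length in bp.
#' @return An object of class `element_spec`.
#' @seealso [build_canonical_element()], [canonical_tirs()]
#' @examples
#' spec <- element_spec()
#' spec
#' @export
element_spec <- function(tir_length = 23L,
                         mismatch_np = 17L,
                         left_tir_inward = "GACATTGTCCACGTCGAGCTACG",
                         right_tir_inward = NULL,
                         orf_length = 858L,
                         minus35_np = c(5L, 10L),
                         minus35_seq = "TTGTCC",
                         minus10_np = c(28L, 33L),
                         minus10_seq = "TATAAT",
                         total_length = 916L) {
  tir_length <- as.integer(tir_length)
  mismatch_np <- as.integer(mismatch_np)
  orf_length <- as.integer(orf_length)
  total_length <- as.integer(total_length)
  minus35_np <- as.integer(minus35_np)
  minus10_np <- as.integer(minus10_np)
  left_tir_inward <- toupper(left_tir_inward)

  if (nchar(left_tir_inward) != tir_length) {
    stop("`left_tir_inward` must have length `tir_length` (", tir_length, ")")
  }
  if (mismatch_np < 1L || mismatch_np > tir_length) {
    stop("`mismatch_np` must lie within the TIR (1..", tir_length, ")")
  }
  if (is.null(right_tir_inward)) {
    lch <- chars(left_tir_inward)
    lch[mismatch_np] <- comp_chars(lch[mismatch_np])
    right_tir_inward <- paste(lch, collapse = "")
  }
  right_tir_inward <- toupper(right_tir_inward)

  spec <- structure(
    list(
      tir_length = tir_length,
      mismatch_np = mismatch_np,
      left_tir_inward = left_tir_inward,
      right_tir_inward = right_tir_inward,
      orf_length = orf_length,
      minus35_np = minus35_np,
      minus35_seq = toupper(minus35_seq),
      minus10_np = minus10_np,
      minus10_seq = toupper(minus10_seq),
      total_length = total_length
    ),
    class = "element_spec"
  )
  validate_element_spec(spec)
  spec
}

validate_element_spec <- function(spec) {
  stopifnot(inherits(spec, "element_spec"))
  tl <- spec$tir_length
  lch <- chars(spec$left_tir_inward)
  rch <- chars(spec$right_tir_inward)
  if (length(rch) != tl) {
    stop("`right_tir_inward` must have length `tir_length`")
  }
  diffs <- which(lch != rch)
  if (!identical(diffs, spec$mismatch_np)) {
    stop("left and right TIR inward reads must differ exactly and only at ",
         "`mismatch_np` (np ", spec$mismatch_np, "); they differ at {",
         paste(diffs, collapse = ","), "}")
  }
  if (spec$orf_length %% 3L != 0L || spec$orf_length < 6L) {
    stop("`orf_length` must be a positive multiple of 3")
  }
  m35 <- spec$minus35_np
  m10 <- spec$minus10_np
  if (diff(m35) != 5L || diff(m10) != 5L) {
    stop("promoter box intervals must span 6 positions")
  }
  if (nchar(spec$minus35_seq) != 6L || nchar(spec$minus10_seq) != 6L) {
    stop("promoter box sequences must be hexamers")
  }
  if (m35[2L] >= m10[1L]) stop("-35 box must precede the -10 box")
  # when the -35 box lies inside the left TIR its sequence must agree with it
  if (m35[2L] <= tl &&
      substr(spec$left_tir_inward, m35[1L], m35[2L]) != spec$minus35_seq) {
    stop("-35 box interval lies inside the left TIR but `left_tir_inward` ",
         "does not carry `minus35_seq` there")
  }
  if (m10[1L] <= tl) {
    stop("defaults place the -10 box downstream of the left TIR; ",
         "`minus10_np` must start beyond `tir_length`")
  }
  # ORF starts right after the -10 box; it must leave the two boundary
  # filler positions before the right TIR free (see build_canonical_element)
  orf_start <- m10[2L] + 1L
  orf_end <- orf_start + spec$orf_length - 1L
  if (orf_end > spec$total_length - tl - 2L) {
    stop("`orf_length` too large: ORF (np ", orf_start, "..", orf_end,
         ") does not fit between the -10 box and the right TIR boundary")
  }
  invisible(spec)
}

# np interval of the ORF implied by a spec (start codon..stop codon)
spec_orf_interval <- function(spec) {
  s <- spec$minus10_np[2L] + 1L
  c(s, s + spec$orf_length - 1L)
}

#' Canonical TIR pair implied by an element specification
#'
#' @param spec An [element_spec()].
#' @return A `tir_pair` object (see [detect_tirs()]) holding the canonical
#'   left/right inward reads and the diagnostic mismatch position.
#' @examples
#' canonical_tirs(element_spec())
#' @export
canonical_tirs <- function(spec = element_spec()) {
  validate_element_spec(spec)
  new_tir_pair(
    length = spec$tir_length,
    left_inward = spec$left_tir_inward,
    right_inward = spec$right_tir_inward
  )
}

#' @export
print.element_spec <- function(x, ...) {
  orf <- spec_orf_interval(x)
  cat("Canonical IS element specification\n")
  cat(sprintf("  total length : %d bp\n", x$total_length))
  cat(sprintf("  TIRs         : %d bp, diagnostic mismatch at np %d (%s/%s)\n",
              x$tir_length, x$mismatch_np,
              substr(x$left_tir_inward, x$mismatch_np, x$mismatch_np),
              substr(x$right_tir_inward, x$mismatch_np, x$mismatch_np)))
  cat(sprintf("  left TIR     : %s\n", x$left_tir_inward))
  cat(sprintf("  right TIR    : %s (inward read)\n", x$right_tir_inward))
  cat(sprintf("  -35 box      : np %d-%d (%s)\n",
              x$minus35_np[1L], x$minus35_np[2L], x$minus35_seq))
  cat(sprintf("  -10 box      : np %d-%d (%s), spacer %d bp\n",
              x$minus10_np[1L], x$minus10_np[2L], x$minus10_seq,
              x$minus10_np[1L] - x$minus35_np[2L] - 1L))
  cat(sprintf("  ORF          : np %d-%d (%d bp, + strand)\n",
              orf[1L], orf[2L], x$orf_length))
  invisible(x)
}
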