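#' Build a canonical IS element sequence
#'
#' Assembles the top strand of a canonical element from an [element_spec()]:
#' left TIR, promoter hexamers, transposase ORF (valid start codon, random
#' sense codons, single in-frame stop at its end) and right TIR, with random
#' filler elsewhere. Every constrained feature is identical across seeds;
#' only the filler (including the ORF's interior codons) varies.
#'
#' Two deliberate sequence-level guards make downstream annotation
#' deterministic:
#'
#' * an in-frame stop codon is placed in the spacer upstream of the ORF
#'   start wherever the promoter boxes leave room, so no upstream start
#'   codon can extend the transposase ORF beyond its designed length;
#' * the filler positions immediately abutting each TIR are chosen
#'   non-complementary across the element ("boundary breakers"), so the
#'   inverted-repeat detector terminates exactly at the TIR boundary
#'   instead of extending into filler by chance (real TIRs are likewise
#'   delimited by divergent flanking sequence).
#'
#' After assembly the element is checked: the longest open reading frame on
#' either strand must be the designed transposase ORF, uniquely; if a random
#' fill violates this the filler is redrawn (deterministically under
#' `seed`).
#'
#' @param spec An [element_spec()].
#' @param seed Integer seed; fully determines the returned sequence.
#' @return A DNA string of length `spec$total_length`.
#' @examples
#' el <- build_canonical_element(element_spec(), seed = 1)
#' nchar(el)
#' @export
build_canonical_element <- function(spec = element_spec(), seed = 1L) {
  validate_element_spec(spec)
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(50L)) {
      el <- assemble_element(spec)
      if (orf_is_dominant(el, spec)) return(el)
    }
    stop("could not realise an element whose transposase ORF is the unique ",
         "longest ORF; the specification leaves too little filler freedom")
  })
}

assemble_element <- function(spec) {
  tl <- spec$tir_length
  len <- spec$total_length
  x <- rep(NA_character_, len)

  x[seq_len(tl)] <- chars(spec$left_tir_inward)
  x[(len - tl + 1L):len] <- chars(revcomp(spec$right_tir_inward))
  x[spec$minus35_np[1L]:spec$minus35_np[2L]] <- chars(spec$minus35_seq)
  x[spec$minus10_np[1L]:spec$minus10_np[2L]] <- chars(spec$minus10_seq)

  orf <- spec_orf_interval(spec)
  n_codons <- spec$orf_length %/% 3L
  x[orf[1L]:(orf[1L] + 2L)] <- c("A", "T", "G")
  if (n_codons > 2L) {
    mid <- random_nonstop_codons(n_codons - 2L)
    x[(orf[1L] + 3L):(orf[2L] - 3L)] <- chars(paste(mid, collapse = ""))
  }
  x[(orf[2L] - 2L):orf[2L]] <- c("T", "A", "A")

  # guard stop codon upstream of (and in frame with) the ORF, in the
  # highest free slot between the left TIR and the promoter boxes
  boxes <- c(spec$minus35_np[1L]:spec$minus35_np[2L],
             spec$minus10_np[1L]:spec$minus10_np[2L])
  p <- orf[1L] - 3L
  while (p > tl) {
    slot <- p:(p + 2L)
    if (!any(slot %in% boxes) && all(is.na(x[slot]))) {
      x[slot] <- c("T", "A", "A")
      break
    }
    p <- p - 3L
  }

  free <- which(is.na(x))
  if (length(free)) x[free] <- sample(DNA_BASES, length(free), replace = TRUE)

  # boundary breakers: the first filler position after each TIR must not
  # pair with its inverted-repeat partner, so detected TIRs end at np
  # `tir_length` exactly
  for (off in c(1L, 2L)) {
    lp <- tl + off                   # pairs with position len - tl - off + 1
    rp <- len - tl - off + 1L
    if (rp %in% free) {
      x[rp] <- sample(setdiff(DNA_BASES, comp_chars(x[lp])), 1L)
    } else if (lp %in% free) {
      x[lp] <- sample(setdiff(DNA_BASES, comp_chars(x[rp])), 1L)
    }
  }
  paste(x, collapse = "")
}

# TRUE when the designed ORF is the unique longest ORF on either strand
orf_is_dominant <- function(element, spec) {
  designed <- spec_orf_interval(spec)
  orfs <- scan_all_orfs(element, min_len = 300L)
  if (nrow(orfs) == 0L) return(FALSE)
  top <- orfs[orfs$length == max(orfs$length), , drop = FALSE]
  nrow(top) == 1L && top$strand == "+" &&
    top$start == designed[1L] && top$end == designed[2L]
}

#' Apply an inversion-process operator to a canonical element
#'
#' Transforms a canonical element into the sequence predicted for each
#' outcome of the inversion process:
#'
#' * `full_ab`: inversion of the entire element (excision/re-integration in
#'   inverted orientation, or TIR-TIR recombination with the conversion
#'   tract upstream of the diagnostic mismatch — indistinguishable at the
#'   sequence level): the whole element is reverse-complemented, so the
#'   inward TIR reads swap (left' = R, right' = L).
#' * `internal_c`: TIR-TIR recombination with the conversion tract
#'   downstream of the diagnostic mismatch: only the segment between
#'   np `mismatch_np + 1` and `len - mismatch_np` is reverse-complemented,
#'   flipping the transposase gene while leaving the TIR configuration
#'   canonical.
#' * `conversion_left_d`: internal inversion with a conversion tract
#'   spanning the mismatch, left TIR used as template: both inward TIR
#'   reads become the canonical left TIR.
#' * `conversion_right_e`: as above with the right TIR as template: both
#'   inward reads become the canonical right TIR.
#' * `excision`: precise loss of the element; returns the empty string (the
#'   caller retains a single target-site copy).
#'
#' The internal breakpoint for `internal_c`/`conversion_left_d`/
#' `conversion_right_e` sits at np `mismatch_np + 1`; any breakpoint between
#' the mismatch and the TIR end yields the same observable TIR
#' configuration, because the inward reads are identical there.
#'
#' @param element Canonical element top strand (DNA string).
#' @param spec The [element_spec()] the element was built from.
#' @param scenario One of `"full_ab"`, `"internal_c"`, `"conversion_left_d"`,
#'   `"conversion_right_e"`, `"excision"`.
#' @return The transformed element (DNA string; empty for `"excision"`).
#' @examples
#' el <- build_canonical_element(element_spec(), seed = 1)
#' inv <- apply_inversion_operator(el, element_spec(), "conversion_left_d")
#' substr(inv, 1, 23) == element_spec()$left_tir_inward
#' @export
apply_inversion_operator <- function(element, spec = element_spec(),
                                     scenario = c("full_ab", "internal_c",
                                                  "conversion_left_d",
                                                  "conversion_right_e",
                                                  "excision")) {
  scenario <- match.arg(scenario)
  validate_element_spec(spec)
  len <- nchar(element)
  if (len < 2L * spec$tir_length) {
    stop("malformed element: shorter than two TIRs (", len, " < ",
         2L * spec$tir_length, ")")
  }
  if (scenario == "excision") return("")
  if (scenario == "full_ab") return(revcomp(element))

  np <- spec$mismatch_np
  inner <- c(np + 1L, len - np)
  out <- paste0(
    substr(element, 1L, inner[1L] - 1L),
    revcomp(substr(element, inner[1L], inner[2L])),
    substr(element, inner[2L] + 1L, len)
  )
  if (scenario == "conversion_left_d") {
    out <- set_tir_reads(out, spec$left_tir_inward)
  } else if (scenario == "conversion_right_e") {
    out <- set_tir_reads(out, spec$right_tir_inward)
  }
  out
}

# overwrite both inward TIR reads of an element with `tir`
set_tir_reads <- function(element, tir) {
  k <- nchar(tir)
  len <- nchar(element)
  paste0(tir, substr(element, k + 1L, len - k), revcomp(tir))
}
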