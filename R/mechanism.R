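#' Classify the inversion mechanism from the TIR configuration
#'
#' Applies the five-outcome decision table that discriminates the possible
#' causes of an IS inversion from the configuration of the element's
#' asymmetric TIRs. With `L` and `R` the canonical left/right inward
#' reads, which differ only at the diagnostic position, each observed
#' inward read is matched at that position:
#'
#' | orientation | left read | right read | class |
#' |---|---|---|---|
#' | canonical | — | — | `not_inverted` |
#' | inverted | R | L | `full_inversion_ab` |
#' | inverted | L | R | `internal_inversion_c` |
#' | inverted | L | L | `conversion_left_d` |
#' | inverted | R | R | `conversion_right_e` |
#' | inverted | neither | any | `unclassified` |
#'
#' `full_inversion_ab` deliberately collapses two mechanisms that are
#' indistinguishable at the sequence level: excision followed by
#' re-integration in inverted orientation, and TIR-TIR recombination with
#' the conversion tract upstream of the diagnostic mismatch.
#' `internal_inversion_c` corresponds to a tract downstream of the
#' mismatch (transposase gene inverted, TIRs untouched), and the two
#' conversion classes to tracts spanning the mismatch with the left or
#' right TIR as template. Absent or ambiguous orientation yields
#' `unclassified`.
#'
#' Matching is keyed on the diagnostic position only; disagreement between
#' the observed and canonical reads elsewhere (point mutations) is
#' recorded in `evidence` and demotes confidence without changing the
#' class.
#'
#' @param observed `tir_pair` of the element copy under test (as laid out
#'   in the genome; no prior reverse complementing).
#' @param canonical `tir_pair` of the canonical element; must carry exactly
#'   one mismatch position (the diagnostic asymmetry) or classification is
#'   impossible.
#' @param orientation The strain's orientation: an `orientation_calls` row,
#'   or one of `"canonical"`, `"inverted"`, `"absent"`, `"ambiguous"`.
#' @param strain_id Optional label carried into the result.
#' @return An object of class `mechanism_call`: fields `strain_id`,
#'   `class`, `left_match`, `right_match` (`"L"`/`"R"`/`"neither"`),
#'   `mismatch_np_used`, `evidence` (character vector).
#' @examples
#' spec <- element_spec()
#' el <- build_canonical_element(spec, seed = 1)
#' inv <- apply_inversion_operator(el, spec, "conversion_left_d")
#' classify_mechanism(detect_tirs(inv), canonical_tirs(spec), "inverted")
#' @export
classify_mechanism <- function(observed, canonical, orientation,
                               strain_id = NA_character_) {
  stopifnot(inherits(observed, "tir_pair"), inherits(canonical, "tir_pair"))
  if (is.data.frame(orientation)) {
    if (!is.na(strain_id) && "strain" %in% names(orientation)) {
      orientation <- orientation[orientation$strain == strain_id, ,
                                 drop = FALSE]
    }
    orientation <- orientation$state[1L]
  }
  orientation <- match.arg(orientation,
                           c("canonical", "inverted", "absent", "ambiguous"))

  if (length(canonical$mismatch_positions) != 1L) {
    stop("no diagnostic asymmetry: canonical TIRs must differ at exactly ",
         "one position (found ", length(canonical$mismatch_positions), ")")
  }
  np <- canonical$mismatch_positions
  l_base <- substr(canonical$left_inward, np, np)
  r_base <- substr(canonical$right_inward, np, np)
  evidence <- character(0)

  match_at_np <- function(read) {
    if (!nzchar(read) || nchar(read) < np) return("neither")
    b <- substr(read, np, np)
    if (b == l_base) "L" else if (b == r_base) "R" else "neither"
  }

  if (orientation %in% c("absent", "ambiguous")) {
    return(new_mechanism_call(strain_id, "unclassified", "neither",
                              "neither", np,
                              paste0("orientation ", orientation,
                                     ": no element configuration to test")))
  }
  if (!observed$found) {
    return(new_mechanism_call(strain_id, "unclassified", "neither",
                              "neither", np, "no TIRs detected"))
  }
  if (observed$length != canonical$length) {
    evidence <- c(evidence, sprintf(
      "observed TIR length %d differs from canonical %d",
      observed$length, canonical$length))
  }

  lm <- match_at_np(observed$left_inward)
  rm <- match_at_np(observed$right_inward)
  evidence <- c(evidence, sprintf(
    "diagnostic np %d: observed left=%s right=%s (L carries %s, R carries %s)",
    np, substr(observed$left_inward, np, np),
    substr(observed$right_inward, np, np), l_base, r_base))

  # full-string agreement, reported but not decisive
  for (side in c("left", "right")) {
    obs <- observed[[paste0(side, "_inward")]]
    eqL <- identical(obs, canonical$left_inward)
    eqR <- identical(obs, canonical$right_inward)
    evidence <- c(evidence, sprintf(
      "%s inward read %s canonical L, %s canonical R (full string)",
      side, if (eqL) "equals" else "differs from",
      if (eqR) "equals" else "differs from"))
  }

  if (orientation == "canonical") {
    cls <- "not_inverted"
  } else if (lm == "R" && rm == "L") {
    cls <- "full_inversion_ab"
    evidence <- c(evidence,
                  paste("excision/re-integration and recombination with an",
                        "upstream conversion tract are indistinguishable"))
  } else if (lm == "L" && rm == "R") {
    cls <- "internal_inversion_c"
  } else if (lm == "L" && rm == "L") {
    cls <- "conversion_left_d"
  } else if (lm == "R" && rm == "R") {
    cls <- "conversion_right_e"
  } else {
    cls <- "unclassified"
  }
  new_mechanism_call(strain_id, cls, lm, rm, np, evidence)
}

new_mechanism_call <- function(strain_id, class, left_match, right_match,
                               np, evidence) {
  structure(
    list(strain_id = strain_id, class = class, left_match = left_match,
         right_match = right_match, mismatch_np_used = np,
         evidence = evidence),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Mechanism call%s: %s\n",
              if (is.na(x$strain_id)) "" else paste0(" [", x$strain_id, "]"),
              x$class))
  cat(sprintf("  left TIR matches %s, right TIR matches %s at np %d\n",
              x$left_match, x$right_match, x$mismatch_np_used))
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Predict the outcome of recombination between two IS copies
#'
#' Ectopic recombination between two co-linear element copies on one
#' replicon deletes the intervening sequence when the copies lie in the
#' same orientation and inverts it when they lie in opposite orientations.
#' Inverting one copy (e.g. by TIR-TIR recombination within it) therefore
#' flips the predicted outcome of a subsequent recombination event with a
#' neighbouring copy.
#'
#' @param orientation_1,orientation_2 Orientations of the two copies,
#'   `"+"` or `"-"`.
#' @return `"deletion"` or `"inversion"`.
#' @examples
#' predict_pair_outcome("+", "+")
#' predict_pair_outcome("+", "-")
#' @export
predict_pair_outcome <- function(orientation_1, orientation_2) {
  orientation_1 <- match.arg(orientation_1, c("+", "-"))
  orientation_2 <- match.arg(orientation_2, c("+", "-"))
  if (orientation_1 == orientation_2) "deletion" else "inversion"
}
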