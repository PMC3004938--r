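new_tir_pair <- function(length, left_inward, right_inward, found = TRUE) {
  mism <- integer(0)
  if (found && length > 0L) {
    mism <- which(chars(left_inward) != chars(right_inward))
  }
  structure(
    list(
      found = found,
      length = as.integer(length),
      left_inward = left_inward,
      right_inward = right_inward,
      mismatch_positions = as.integer(mism)
    ),
    class = "tir_pair"
  )
}

#' @export
print.tir_pair <- function(x, ...) {
  if (!x$found) {
    cat("TIR pair: none found\n")
    return(invisible(x))
  }
  cat(sprintf("TIR pair (%d bp inward reads)\n", x$length))
  cat(sprintf("  left  : %s\n", x$left_inward))
  cat(sprintf("  right : %s\n", x$right_inward))
  if (length(x$mismatch_positions)) {
    cat(sprintf("  mismatches at np %s\n",
                paste(x$mismatch_positions, collapse = ", ")))
  } else {
    cat("  reads identical\n")
  }
  invisible(x)
}

#' Detect terminal inverted repeats de novo
#'
#' Compares the element's prefix with the reverse complement of its suffix
#' and reports the longest terminal inverted repeat: the largest
#' `k` in `[k_min, min(k_max, len/2)]` such that the two inward reads of
#' length `k` differ at no more than `d_max` positions *and* agree at
#' position `k` itself. The terminal-match condition trims trailing
#' mismatches, so a reported repeat never ends on a mismatched position and
#' the detector stops at the repeat/filler boundary instead of absorbing up
#' to `d_max` positions of flanking sequence.
#'
#' The default mismatch budget `d_max = 2` accommodates the diagnostic
#' left/right asymmetry plus one point mutation.
#'
#' @param element DNA string (one element copy, ungapped).
#' @param k_min,k_max Smallest/largest repeat length considered (bp).
#' @param d_max Maximum number of mismatched positions tolerated between
#'   the two inward reads.
#' @return A `tir_pair`: inward reads of both TIRs, their common length and
#'   the sorted mismatch catalogue (1-based np, counted from the element's
#'   outer end). When no length qualifies, a `tir_pair` with `found = FALSE`
#'   is returned (distinct from an error).
#' @examples
#' el <- build_canonical_element(element_spec(), seed = 1)
#' detect_tirs(el)
#' @export
detect_tirs <- function(element, k_min = 10L, k_max = 50L, d_max = 2L) {
  n <- nchar(element)
  if (n < 2L * k_min) {
    stop("malformed element: length ", n, " < 2 * k_min = ", 2L * k_min)
  }
  kx <- min(as.integer(k_max), n %/% 2L)
  x <- chars(element)
  left <- x[seq_len(kx)]
  # inward read of the right TIR: complement of the top strand, outer->inner
  right <- comp_chars(x[n:(n - kx + 1L)])
  mism <- left != right
  ok <- cumsum(mism) <= d_max & !mism
  ks <- which(ok)
  ks <- ks[ks >= k_min]
  if (!length(ks)) {
    return(new_tir_pair(0L, "", "", found = FALSE))
  }
  k <- max(ks)
  new_tir_pair(
    length = k,
    left_inward = paste(left[seq_len(k)], collapse = ""),
    right_inward = paste(right[seq_len(k)], collapse = "")
  )
}

# all ORFs >= min_len on both strands; coordinates on the top strand
scan_all_orfs <- function(element, min_len = 300L) {
  n <- nchar(element)
  res <- list(
    orfs_one_strand(element, min_len),
    orfs_one_strand(revcomp(element), min_len)
  )
  fwd <- res[[1L]]
  rev <- res[[2L]]
  if (nrow(fwd)) fwd$strand <- "+"
  if (nrow(rev)) {
    # map minus-strand coordinates back onto the top strand
    s <- n - rev$end + 1L
    e <- n - rev$start + 1L
    rev$start <- s
    rev$end <- e
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (!nrow(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), strand = character(0)))
  }
  out[order(out$strand, out$start), , drop = FALSE]
}

# ORFs on the given strand of `seq`, coordinates in `seq` itself; per
# frame, each stop codon is paired with the first start codon after the
# preceding stop
orfs_one_strand <- function(seq, min_len) {
  x <- chars(seq)
  n <- length(x)
  out <- list()
  for (frame in 0:2) {
    nc <- (n - frame) %/% 3L
    if (nc < 2L) next
    starts_at <- seq.int(frame + 1L, by = 3L, length.out = nc)
    codons <- paste0(x[starts_at], x[starts_at + 1L], x[starts_at + 2L])
    stop_i <- which(codons %in% STOP_CODONS)
    start_i <- which(codons %in% START_CODONS)
    if (!length(stop_i) || !length(start_i)) next
    prev_stop <- c(0L, stop_i[-length(stop_i)])
    k <- findInterval(prev_stop, start_i) + 1L   # first start after prev stop
    ok <- k <= length(start_i)
    first_start <- start_i[pmin(k, length(start_i))]
    valid <- ok & first_start < stop_i
    if (!any(valid)) next
    s <- starts_at[first_start[valid]]
    e <- starts_at[stop_i[valid]] + 2L
    keep <- (e - s + 1L) >= min_len
    if (any(keep)) {
      out[[length(out) + 1L]] <- cbind(s[keep], e[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L], length = m[, 2L] - m[, 1L] + 1L)
}

#' Locate the transposase open reading frame
#'
#' Returns the longest open reading frame of at least `min_len` bp on
#' either strand: a start codon (ATG/GTG/TTG, the common bacterial set)
#' followed in frame by sense codons and ending at the first stop codon.
#' Length includes the stop codon. Ties are broken in favour of the top
#' strand, then the leftmost start (top-strand coordinates).
#'
#' @param element DNA string.
#' @param min_len Minimum ORF length in bp (start through stop).
#' @return `list(interval = c(start, end), length, strand)` in 1-based
#'   top-strand coordinates, or `NULL` when no qualifying ORF exists.
#' @examples
#' el <- build_canonical_element(element_spec(), seed = 1)
#' find_transposase_orf(el)
#' @export
find_transposase_orf <- function(element, min_len = 300L) {
  orfs <- scan_all_orfs(element, min_len = min_len)
  if (!nrow(orfs)) return(NULL)
  orfs <- orfs[order(-orfs$length, orfs$strand != "+", orfs$start), ,
               drop = FALSE]
  top <- orfs[1L, ]
  list(interval = c(top$start, top$end), length = top$length,
       strand = top$strand)
}

#' Detect the target-site duplication flanking an element
#'
#' Upon insertion the element duplicates its target site, leaving identical
#' direct repeats immediately abutting both element ends. The detector
#' compares the terminal `n`-mer of the left flank with the initial
#' `n`-mer of the right flank and reports the longest exact match with
#' `n` in `[n_min, n_max]`.
#'
#' @param left_flank Ungapped sequence immediately 5' of the element.
#' @param right_flank Ungapped sequence immediately 3' of the element.
#' @param n_min,n_max Repeat lengths considered (bp).
#' @return `list(sequence, length, target_site_match)` where
#'   `target_site_match` is `TRUE` iff the repeat is a 3-mer matching the
#'   T(T/A)A target-site motif; `NULL` when no shared terminal n-mer
#'   exists.
#' @examples
#' detect_tsd("GCGATTA", "TTACGGC")
#' @export
detect_tsd <- function(left_flank, right_flank, n_min = 2L, n_max = 10L) {
  ll <- nchar(left_flank)
  rl <- nchar(right_flank)
  if (ll < n_min || rl < n_min) {
    stop("malformed input: flank shorter than n_min = ", n_min)
  }
  for (n in seq.int(min(n_max, ll, rl), n_min)) {
    l <- substr(left_flank, ll - n + 1L, ll)
    r <- substr(right_flank, 1L, n)
    if (l == r) {
      return(list(
        sequence = l,
        length = n,
        target_site_match = n == 3L && grepl("^T[TA]A$", l)
      ))
    }
  }
  NULL
}

# consensus handling: conserved positions must match exactly, the rest are
# "soft" and share a mismatch budget
hexamer_score <- function(hex, consensus, conserved, max_soft) {
  h <- chars(hex)
  cs <- chars(consensus)
  if (any(h[conserved] != cs[conserved])) return(NA_integer_)
  soft <- setdiff(seq_len(6L), conserved)
  mm <- sum(h[soft] != cs[soft])
  if (mm > max_soft) return(NA_integer_)
  6L - mm
}

#' Scan for sigma-70 promoter boxes near the element's 5' end
#'
#' Enumerates every (-35, -10) hexamer pair within the first
#' `search_window` nucleotides of the element and keeps pairs where the
#' -35 matches the T*T*G*ACA consensus (asterisked positions 1, 2, 3
#' exact; at most `max_soft_mismatches` among the rest), the -10 matches
#' T*A*TAAT* (positions 1, 2, 6 exact), and the spacer between them lies
#' in `spacer_range`. Hits are ranked by total matched consensus positions
#' (0-12) descending, then by closeness of the spacer to the canonical
#' 17 bp, then by leftmost -35 and leftmost -10.
#'
#' Under this reading of the consensus notation the -35 hexamer TTGTCC is
#' a valid hit (its two mismatches to TTGACA fall on non-conserved
#' positions), consistent with its annotation inside the left TIR of the
#' canonical element.
#'
#' @param element DNA string (at least `search_window` nt).
#' @param search_window Window at the element's 5' end (nt) within which
#'   both hexamers must lie.
#' @param spacer_range Inclusive range of admissible spacer lengths (bp).
#' @param max_soft_mismatches Mismatch budget at non-conserved positions,
#'   per hexamer.
#' @return A data frame of hits (possibly empty) with columns
#'   `minus35_start`, `minus35_end`, `minus35_seq`, `minus10_start`,
#'   `minus10_end`, `minus10_seq`, `spacer`, `score`, ranked best first.
#'   Coordinates are 1-based np relative to the element start.
#' @examples
#' el <- build_canonical_element(element_spec(), seed = 1)
#' scan_promoters(el)[1, ]
#' @export
scan_promoters <- function(element, search_window = 60L,
                           spacer_range = c(15L, 19L),
                           max_soft_mismatches = 2L) {
  if (nchar(element) < search_window) {
    stop("element shorter than `search_window` (", search_window, " nt)")
  }
  win <- substr(element, 1L, search_window)
  hits <- list()
  for (s1 in seq_len(search_window - 6L + 1L)) {
    h35 <- substr(win, s1, s1 + 5L)
    sc35 <- hexamer_score(h35, "TTGACA", c(1L, 2L, 3L), max_soft_mismatches)
    if (is.na(sc35)) next
    for (spacer in seq.int(spacer_range[1L], spacer_range[2L])) {
      s2 <- s1 + 6L + spacer
      if (s2 + 5L > search_window) next
      h10 <- substr(win, s2, s2 + 5L)
      sc10 <- hexamer_score(h10, "TATAAT", c(1L, 2L, 6L), max_soft_mismatches)
      if (is.na(sc10)) next
      hits[[length(hits) + 1L]] <- data.frame(
        minus35_start = s1, minus35_end = s1 + 5L, minus35_seq = h35,
        minus10_start = s2, minus10_end = s2 + 5L, minus10_seq = h10,
        spacer = spacer, score = sc35 + sc10
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(
      minus35_start = integer(0), minus35_end = integer(0),
      minus35_seq = character(0), minus10_start = integer(0),
      minus10_end = integer(0), minus10_seq = character(0),
      spacer = integer(0), score = integer(0)
    ))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$score, abs(out$spacer - 17L),
                   out$minus35_start, out$minus10_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate one element copy
#'
#' Runs the four anatomy detectors on a single ungapped element copy:
#' TIRs ([detect_tirs()]), transposase ORF ([find_transposase_orf()]),
#' flanking target-site duplication ([detect_tsd()], when flanks are
#' supplied) and promoter boxes ([scan_promoters()]).
#'
#' @param element Ungapped element sequence (DNA string).
#' @param left_flank,right_flank Ungapped flanking sequence immediately
#'   abutting the element (may be empty, in which case no TSD is called).
#' @param strain_id Optional strain label carried through to the result.
#' @param element_interval Optional 1-based interval of the element in the
#'   strain's ungapped coordinates (carried through, not checked).
#' @param orf_min_len Minimum ORF length passed to
#'   [find_transposase_orf()].
#' @return An object of class `annotated_element` with fields `strain_id`,
#'   `element_interval`, `length`, `tirs`, `orf`, `tsd`, `promoters`.
#' @examples
#' el <- build_canonical_element(element_spec(), seed = 1)
#' ann <- annotate_element(el, left_flank = "GCGTTA", right_flank = "TTAGCC")
#' ann$tsd$sequence
#' @export
annotate_element <- function(element, left_flank = "", right_flank = "",
                             strain_id = NA_character_,
                             element_interval = NULL,
                             orf_min_len = 300L) {
  tsd <- NULL
  if (nzchar(left_flank) && nzchar(right_flank)) {
    tsd <- detect_tsd(left_flank, right_flank)
  }
  structure(
    list(
      strain_id = strain_id,
      element_interval = element_interval %||% c(1L, nchar(element)),
      length = nchar(element),
      tirs = detect_tirs(element),
      orf = find_transposase_orf(element, min_len = orf_min_len),
      tsd = tsd,
      promoters = scan_promoters(element)
    ),
    class = "annotated_element"
  )
}

#' @export
print.annotated_element <- function(x, ...) {
  cat(sprintf("Annotated IS element%s (%d bp)\n",
              if (is.na(x$strain_id)) "" else paste0(" [", x$strain_id, "]"),
              x$length))
  if (x$tirs$found) {
    cat(sprintf("  TIRs     : %d bp, mismatches at np {%s}\n", x$tirs$length,
                paste(x$tirs$mismatch_positions, collapse = ",")))
  } else {
    cat("  TIRs     : none found\n")
  }
  if (!is.null(x$orf)) {
    cat(sprintf("  ORF      : %d-%d (%d bp, %s strand)\n",
                x$orf$interval[1L], x$orf$interval[2L], x$orf$length,
                x$orf$strand))
  } else {
    cat("  ORF      : none\n")
  }
  if (!is.null(x$tsd)) {
    cat(sprintf("  TSD      : %s%s\n", x$tsd$sequence,
                if (x$tsd$target_site_match) " (T(T/A)A target site)" else ""))
  } else {
    cat("  TSD      : none\n")
  }
  if (nrow(x$promoters)) {
    h <- x$promoters[1L, ]
    cat(sprintf(
      "  promoter : -35 %s @ %d-%d, -10 %s @ %d-%d, spacer %d (score %d)\n",
      h$minus35_seq, h$minus35_start, h$minus35_end,
      h$minus10_seq, h$minus10_start, h$minus10_end, h$spacer, h$score))
  } else {
    cat("  promoter : no hit\n")
  }
  invisible(x)
}

#' Write an element annotation as GFF3
#'
#' Emits the annotated features (element span, both TIRs, transposase ORF,
#' TSD copies, promoter boxes of the top-ranked hit) as a GFF3 file in the
#' strain's ungapped coordinates. Requires the optional packages
#' `GenomicRanges` and `rtracklayer`.
#'
#' @param ann An [annotate_element()] result.
#' @param file Output path.
#' @param seqid Sequence identifier for column 1; defaults to the strain id.
#' @return The path, invisibly.
#' @export
write_annotation_gff3 <- function(ann, file, seqid = NULL) {
  stopifnot(inherits(ann, "annotated_element"))
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GFF3 output requires the GenomicRanges and rtracklayer packages")
  }
  seqid <- seqid %||% (if (is.na(ann$strain_id)) "element" else ann$strain_id)
  off <- ann$element_interval[1L] - 1L
  feats <- list(list(type = "mobile_genetic_element",
                     start = 1L, end = ann$length, strand = "+"))
  if (ann$tirs$found) {
    k <- ann$tirs$length
    feats <- c(feats, list(
      list(type = "terminal_inverted_repeat", start = 1L, end = k,
           strand = "+"),
      list(type = "terminal_inverted_repeat", start = ann$length - k + 1L,
           end = ann$length, strand = "-")
    ))
  }
  if (!is.null(ann$orf)) {
    feats <- c(feats, list(list(type = "CDS", start = ann$orf$interval[1L],
                                end = ann$orf$interval[2L],
                                strand = ann$orf$strand)))
  }
  if (nrow(ann$promoters)) {
    h <- ann$promoters[1L, ]
    feats <- c(feats, list(
      list(type = "minus_35_signal", start = h$minus35_start,
           end = h$minus35_end, strand = "+"),
      list(type = "minus_10_signal", start = h$minus10_start,
           end = h$minus10_end, strand = "+")
    ))
  }
  df <- do.call(rbind, lapply(feats, as.data.frame))
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = df$start + off, end = df$end + off),
    strand = df$strand,
    type = df$type,
    phase = ifelse(df$type == "CDS", 0L, NA_integer_)
  )
  if (!is.null(ann$tsd)) {
    n <- ann$tsd$length
    tsd <- GenomicRanges::GRanges(
      seqnames = seqid,
      ranges = IRanges::IRanges(
        start = c(ann$element_interval[1L] - n,
                  ann$element_interval[2L] + 1L),
        width = n
      ),
      strand = "+",
      type = "direct_repeat",
      phase = NA_integer_
    )
    gr <- c(gr, tsd)
  }
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}
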