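#' Read a per-locus multi-strain alignment
#'
#' Parses an aligned multi-FASTA (gap character `-`) into a validated
#' `locus_alignment`. The element interval (alignment columns) may be
#' given directly or read from the JSON metadata sidecar written by
#' [write_sim()] (`<stem>.meta.json` next to the FASTA), which also
#' supplies the reference strain when omitted.
#'
#' @param path Aligned multi-FASTA file, or a named character vector of
#'   aligned rows (then no sidecar lookup happens).
#' @param reference_strain Strain carrying the canonical element copy.
#' @param element_interval 1-based inclusive alignment-column interval of
#'   the element in the reference strain.
#' @param locus_id Optional locus label; defaults to the file stem.
#' @return An object of class `locus_alignment`: fields `locus_id`,
#'   `strains` (named character vector, uppercased), `reference_strain`,
#'   `element_interval`.
#' @examples
#' sim <- simulate_locus(sim_config(n_strains = 6, seed = 3))
#' dir <- tempfile(); paths <- write_sim(sim, dir)
#' aln <- read_locus_alignment(paths[["fasta"]])
#' aln
#' @export
read_locus_alignment <- function(path, reference_strain = NULL,
                                 element_interval = NULL, locus_id = NULL) {
  if (is.character(path) && length(path) == 1L && is.null(names(path))) {
    if (!file.exists(path)) stop("file not found: ", path)
    meta_path <- paste0(sub("\\.(fa|fasta|fna)$", "", path), ".meta.json")
    if (file.exists(meta_path) &&
        (is.null(reference_strain) || is.null(element_interval))) {
      meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
      reference_strain <- reference_strain %||% meta$reference_strain
      element_interval <- element_interval %||% meta$element_interval
      locus_id <- locus_id %||% meta$locus_id
    }
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop("format error: ",
                                             conditionMessage(e)))
    if (length(set) == 0L) stop("format error: empty alignment file")
    strains <- toupper(as.character(set))
    names(strains) <- sub("\\s.*$", "", names(set))
    locus_id <- locus_id %||% sub("\\.[^.]*$", "", basename(path))
  } else {
    strains <- toupper(path)
    locus_id <- locus_id %||% "locus"
  }

  if (anyDuplicated(names(strains))) {
    stop("duplicate strain ids: ",
         paste(unique(names(strains)[duplicated(names(strains))]),
               collapse = ", "))
  }
  widths <- nchar(strains)
  if (length(unique(widths)) != 1L) {
    stop("format error: ragged alignment (row lengths ",
         paste(sort(unique(widths)), collapse = ", "), ")")
  }
  if (is.null(reference_strain) || is.null(element_interval)) {
    stop("`reference_strain` and `element_interval` are required when no ",
         "metadata sidecar is available")
  }
  if (!reference_strain %in% names(strains)) {
    stop("lookup error: reference strain '", reference_strain,
         "' not in alignment")
  }
  element_interval <- as.integer(element_interval)
  if (length(element_interval) != 2L ||
      element_interval[1L] <= 1L || element_interval[2L] >= widths[1L] ||
      element_interval[1L] > element_interval[2L]) {
    stop("`element_interval` must lie strictly inside the alignment ",
         "(flanks must exist on both sides)")
  }
  ref <- strains[[reference_strain]]
  if (substr(ref, element_interval[1L], element_interval[1L]) == "-" ||
      substr(ref, element_interval[2L], element_interval[2L]) == "-") {
    stop("reference strain has a gap at an element boundary column")
  }

  structure(
    list(
      locus_id = locus_id,
      strains = strains,
      reference_strain = reference_strain,
      element_interval = element_interval
    ),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("Locus alignment '%s': %d strains x %d columns\n",
              x$locus_id, length(x$strains), nchar(x$strains[[1L]])))
  cat(sprintf("  element columns %d-%d, reference strain %s\n",
              x$element_interval[1L], x$element_interval[2L],
              x$reference_strain))
  invisible(x)
}

#' Extract the ungapped sequence of an alignment slice
#'
#' Removes gap characters from one strain's row over a column interval and
#' returns the sequence together with an exact two-way coordinate map.
#' Ungapped positions are 1-based in the strain's full ungapped sequence
#' (counting non-gap characters from column 1), so extracted coordinates
#' stay comparable across intervals.
#'
#' @param aln A [read_locus_alignment()] result.
#' @param strain_id Strain to extract.
#' @param column_interval 1-based inclusive alignment-column interval;
#'   defaults to the whole alignment.
#' @return `list(seq, map)` where `map` is a data frame with one row per
#'   non-gap column in the interval (`column`, `position`).
#' @examples
#' aln <- read_locus_alignment(c(ref = "A-C-G", alt = "AACTG"),
#'                             reference_strain = "ref",
#'                             element_interval = c(3, 3))
#' extract_ungapped(aln, "ref", c(1, 5))
#' @export
extract_ungapped <- function(aln, strain_id, column_interval = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (!strain_id %in% names(aln$strains)) {
    stop("lookup error: unknown strain '", strain_id, "'")
  }
  row <- chars(aln$strains[[strain_id]])
  nc <- length(row)
  ci <- as.integer(column_interval %||% c(1L, nc))
  if (ci[1L] < 1L || ci[2L] > nc || ci[1L] > ci[2L]) {
    stop("`column_interval` outside the alignment")
  }
  pos_all <- cumsum(row != "-")          # ungapped position per column
  cols <- ci[1L]:ci[2L]
  keep <- cols[row[cols] != "-"]
  list(
    seq = paste(row[keep], collapse = ""),
    map = data.frame(column = keep, position = pos_all[keep])
  )
}

#' Call per-strain element presence and orientation
#'
#' For each strain the fraction of non-gap characters over the element
#' columns decides presence: `absent` at or below `absent_max`, present at
#' or above `present_min`, `ambiguous` in between (partially deleted or
#' poorly determined copies). For present strains the ungapped element
#' region is extracted and the transposase ORF strand determined; the call
#' is `canonical` when the strand matches the reference element's ORF
#' strand and `inverted` when it is opposite. A present strain without a
#' detectable ORF is `ambiguous`.
#'
#' Orientation is deliberately decided by ORF strand rather than TIR
#' order: recombination with a conversion tract downstream of the
#' diagnostic mismatch inverts the transposase gene while leaving the TIR
#' configuration canonical, and must still be called inverted.
#'
#' @param aln A [read_locus_alignment()] result.
#' @param canonical Optional [annotate_element()] result for the reference
#'   element; computed from the reference strain when omitted.
#' @param absent_max,present_min Non-gap-fraction thresholds.
#' @param orf_min_len Minimum ORF length (bp) for strand determination.
#' @return A data frame of class `orientation_calls` with columns `strain`,
#'   `state` (`absent`/`canonical`/`inverted`/`ambiguous`),
#'   `non_gap_fraction`, `orf_strand` (`+`/`-`/`none`).
#' @examples
#' sim <- simulate_locus(sim_config(n_strains = 8, seed = 5,
#'                                  mutation_rate = 0))
#' aln <- read_locus_alignment(sim$alignment,
#'                             reference_strain = sim$reference_strain,
#'                             element_interval = sim$element_interval)
#' call_presence_orientation(aln)
#' @export
call_presence_orientation <- function(aln, canonical = NULL,
                                      absent_max = 0.10, present_min = 0.50,
                                      orf_min_len = 300L) {
  stopifnot(inherits(aln, "locus_alignment"))
  ei <- aln$element_interval

  if (is.null(canonical)) {
    ref <- extract_ungapped(aln, aln$reference_strain, ei)
    canonical <- annotate_element(ref$seq, strain_id = aln$reference_strain,
                                  orf_min_len = orf_min_len)
  }
  if (is.null(canonical$orf)) {
    stop("reference element has no detectable transposase ORF; cannot ",
         "anchor orientation")
  }
  ref_strand <- canonical$orf$strand

  calls <- lapply(names(aln$strains), function(sid) {
    row_el <- substr(aln$strains[[sid]], ei[1L], ei[2L])
    nch <- chars(row_el)
    frac <- mean(nch != "-")
    state <- "ambiguous"
    strand <- "none"
    if (frac <= absent_max) {
      state <- "absent"
    } else if (frac >= present_min) {
      seq_el <- paste(nch[nch != "-"], collapse = "")
      orf <- if (nchar(seq_el) >= orf_min_len)
        find_transposase_orf(seq_el, min_len = orf_min_len) else NULL
      if (is.null(orf)) {
        state <- "ambiguous"
      } else {
        strand <- orf$strand
        state <- if (strand == ref_strand) "canonical" else "inverted"
      }
    }
    data.frame(strain = sid, state = state, non_gap_fraction = frac,
               orf_strand = strand)
  })
  out <- do.call(rbind, calls)
  class(out) <- c("orientation_calls", class(out))
  out
}
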