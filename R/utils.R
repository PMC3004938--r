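#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N,-}` alphabet.
#' Gap characters are preserved (the complement of `-` is `-`), so the
#' function can be applied to aligned rows as well as ungapped sequences.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp("GATTA")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# split one string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# complement of a character vector of bases (gaps preserved)
comp_chars <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[x])
}

# hamming distance between equal-length character vectors
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a != b)
}

# random DNA string of length n (caller controls the RNG seed)
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# n random sense codons, excluding stop codons
random_nonstop_codons <- function(n) {
  if (n <= 0L) return(character(0))
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                      paste, collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  sample(sense, n, replace = TRUE)
}

# write a named character vector of (possibly gapped) sequences as FASTA
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
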