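#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the ACGTN alphabet (N maps to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Canonical form of a DNA sequence
#'
#' The lexicographic minimum of a sequence and its reverse complement, the
#' orientation-free representative used for k-mers and emitted contigs.
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
canonical <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param len length (recycled).
#' @return character vector of i.i.d. uniform ACGT sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# all k-mers of one sequence (character vector; empty if too short)
kmers_of <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

# enforce scalar logical/numeric arguments
stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
  }
  invisible(x)
}
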