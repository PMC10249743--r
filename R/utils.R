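#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param len integer length, recycled to `n`.
#' @return character vector of uppercase ACGT strings.
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over ACGTN.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' The seven-level biotype hierarchy
#'
#' Order in which biotype references are searched: the first level with a
#' perfect sense-strand hit wins.
#' @export
BIOTYPE_HIERARCHY <- c("rRNA", "mt-tRNA", "tRNA", "miRNA", "lncRNA",
                       "piRNA", "protein_coding")

#' NEBNext 3' adapter used for small RNA libraries
#' @export
NEB_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' tsRNA subtype labels
#'
#' The five cut-site subtypes plus the whole-tRNA bucket for full-length
#' reads (excluded from five-subtype tallies but retained in counts).
#' @export
TSRNA_SUBTYPES <- c("five_half", "five_tsRNA", "i_tsRNA", "three_tsRNA",
                    "three_half")

#' @rdname TSRNA_SUBTYPES
#' @export
TSRNA_SUBTYPES_ALL <- c(TSRNA_SUBTYPES, "whole_tRNA")

# any of a being a substring of any of b (or vice versa)?
has_substring_conflict <- function(new, existing) {
  if (length(existing) == 0L) return(FALSE)
  any(vapply(existing, function(e) {
    grepl(new, e, fixed = TRUE) || grepl(e, new, fixed = TRUE)
  }, logical(1)))
}

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
}
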