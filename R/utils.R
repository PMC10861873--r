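#' @useDynLib crispacer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats p.adjust rnbinom rpois rlnorm runif t.test setNames
#' @importFrom utils read.table write.table modifyList head combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> set of concrete bases (used by validation and the tests'
# brute-force oracles; actual motif matching goes through Biostrings)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' IUPAC ambiguity codes are complemented correctly.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_valid_iupac <- function(motif) {
  all(strsplit(motif, "")[[1]] %in% names(IUPAC_SETS))
}

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

# 0-based half-open -> 1-based inclusive (for report output)
to_one_based <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
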