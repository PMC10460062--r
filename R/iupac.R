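# IUPAC nucleotide ambiguity machinery shared by the matcher, the simulator
# and the primer-panel validators. Bases are bit-encoded (A=1, C=2, G=4, T=8)
# so "sequence base compatible with code" is a single bitwAnd.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_BITS <- vapply(.IUPAC_SETS, function(s) sum(.BASE_BITS[s]), integer(1))

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

iupac_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

check_iupac <- function(x, what = "primer") {
  ch <- iupac_chars(x)
  bad <- setdiff(unique(ch), names(.IUPAC_SETS))
  if (nchar(x) == 0L) {
    stop(what, " sequence is empty", call. = FALSE)
  }
  if (length(bad) > 0L) {
    stop(
      what, " contains non-IUPAC characters: ",
      paste(bad, collapse = ", "), call. = FALSE
    )
  }
  invisible(x)
}

# Bit mask per primer position (U normalized to T by the code table).
iupac_mask <- function(primer) {
  check_iupac(primer)
  unname(.IUPAC_BITS[iupac_chars(primer)])
}

# Bit encoding of a concrete {A,C,G,T} sequence.
encode_bases <- function(sequence) {
  ch <- iupac_chars(sequence)
  bits <- .BASE_BITS[ch]
  if (anyNA(bits)) {
    bad <- unique(ch[is.na(bits)])
    stop(
      "sequence contains characters outside {A,C,G,T}: ",
      paste(bad, collapse = ", "), call. = FALSE
    )
  }
  unname(bits)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements ambiguity codes correctly (R<->Y, K<->M, B<->V, D<->H,
#' S/W/N self-complementary) and reverses the sequence. `U` is treated as `T`.
#'
#' @param x A character vector of IUPAC nucleotide strings.
#' @return A character vector of the same length.
#' @examples
#' reverse_complement("AGAGTTTGATYMTGGCTCAG")
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    check_iupac(s, what = "sequence")
    paste(rev(.IUPAC_COMPLEMENT[iupac_chars(s)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Number of concrete expansions of a degenerate primer
#'
#' The degeneracy of an IUPAC primer is the product over positions of the
#' size of each code's base set, i.e. the number of distinct concrete
#' oligonucleotides the degenerate sequence stands for.
#'
#' @param primer An IUPAC nucleotide string.
#' @return A single integer.
#' @examples
#' degeneracy("AGAGTTTGATYMTGGCTCAG") # Y x M -> 4
#' degeneracy("ACGT")                 # 1
#' @export
degeneracy <- function(primer) {
  check_iupac(primer)
  prod(lengths(.IUPAC_SETS[iupac_chars(primer)]))
}

# All concrete realizations of a degenerate primer (used for site planting;
# kept internal -- tests carry their own expansion oracle).
iupac_expand <- function(primer) {
  check_iupac(primer)
  sets <- .IUPAC_SETS[iupac_chars(primer)]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}
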