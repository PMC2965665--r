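# IUPAC nucleotide alphabet and degenerate-base set semantics.

#' IUPAC nucleotide base sets
#'
#' Named list mapping every IUPAC nucleotide code (including the four
#' unambiguous bases and `N`) to the set of unambiguous bases it denotes.
#' The gap character `-` is not part of the alphabet; it is only legal in
#' aligned sequences and never matches a base.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- names(IUPAC_SETS)

# 4-bit encoding of the base set behind each code: A=1, C=2, G=4, T=8.
.iupac_bits <- vapply(IUPAC_SETS, function(s) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[s])
}, integer(1))

#' Do two IUPAC codes match?
#'
#' Symmetric set-intersection semantics: two codes match when the base
#' sets they denote intersect. `N` matches everything; `S` vs `W` do not
#' match because \{G,C\} and \{A,T\} are disjoint. Vectorised over both
#' arguments.
#'
#' @param a,b Character vectors of single IUPAC codes.
#' @return Logical vector.
#' @examples
#' iupac_match("W", "A")  # TRUE
#' iupac_match("S", "W")  # FALSE
#' @export
iupac_match <- function(a, b) {
  ba <- .iupac_bits[a]
  bb <- .iupac_bits[b]
  if (anyNA(ba) || anyNA(bb)) {
    bad <- unique(c(a[is.na(ba)], b[is.na(bb)]))
    stop("non-IUPAC character(s): ", paste(bad, collapse = ", "))
  }
  bitwAnd(ba, bb) > 0L
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet (`R`<->`Y`, `K`<->`M`, `B`<->`V`,
#' `D`<->`H`; `S`, `W` and `N` are self-complementary) and preserves gap
#' characters in aligned input.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N", "-" = "-")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    out <- comp[ch]
    if (anyNA(out)) stop("non-IUPAC character in sequence")
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split sequences into a character matrix (rows = sequences). All inputs
# must have equal length.
.seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("sequences have unequal lengths; an alignment is required")
  ch <- strsplit(seqs, "", fixed = TRUE)
  matrix(unlist(ch), nrow = length(seqs), byrow = TRUE,
         dimnames = list(names(seqs), NULL))
}
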