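# Translation under the invertebrate mitochondrial genetic code
# (NCBI translation table 5) and numt screening: internal stop codons,
# frameshift signatures, and amino-acid indels against an alignment
# consensus.

.codon_table_5 <- local({
  # Table 5 differs from the standard code at: TGA->W, AGA->S, AGG->S,
  # ATA->M. Stops are TAA and TAG only.
  b <- c("T", "C", "A", "G")
  # first codon position slowest, third fastest (TTT, TTC, TTA, ...)
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L),
                   rep(b, 16L))
  # Standard code laid out in TCAG order on all three positions.
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG"),  # GTT..GGG
    "")[[1]]
  names(aa) <- codons
  aa["TGA"] <- "W"; aa["AGA"] <- "S"; aa["AGG"] <- "S"; aa["ATA"] <- "M"
  aa
})

#' The invertebrate mitochondrial genetic code
#'
#' Complete 64-codon map of NCBI translation table 5. Differs from the
#' standard code at `TGA` (Trp), `AGA`/`AGG` (Ser) and `ATA` (Met);
#' the only stop codons are `TAA` and `TAG`. Stops are rendered `*`.
#'
#' @return Named character vector of length 64 (codon -> one-letter
#'   amino acid or `*`).
#' @export
invert_mito_code <- function() .codon_table_5

# Translate a vector of codon strings; any codon containing a non-ACGT
# character (ambiguity code or gap) yields 'X' and never counts as stop.
.translate_codons <- function(codons, code) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.codons_of <- function(nt, frame) {
  usable <- nchar(nt) - frame
  n_codons <- usable %/% 3L
  if (n_codons < 1L)
    stop("sequence shorter than one codon in frame ", frame)
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  substring(nt, starts, starts + 2L)
}

#' Translate a nucleotide sequence
#'
#' Translates in the given frame (0, 1 or 2 skipped bases) and strand
#' under a genetic code; the trailing partial codon is ignored. Codons
#' containing ambiguity codes or gaps translate to `X`; stop codons are
#' rendered `*`.
#'
#' @param nt Single nucleotide string.
#' @param code Codon map, default [invert_mito_code()].
#' @param frame Integer 0, 1 or 2.
#' @param strand `"+"` (as given) or `"-"` (reverse complement first).
#' @return Amino-acid string.
#' @examples
#' translate_dna("ATACAT")  # "MH" -- ATA is Met under table 5
#' @export
translate_dna <- function(nt, code = invert_mito_code(), frame = 0L,
                          strand = "+") {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") nt <- reverse_complement(nt)
  paste(.translate_codons(.codons_of(nt, as.integer(frame)), code),
        collapse = "")
}

.count_internal_stops <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  # A terminal stop is ordinary for a fragment ending at the gene end;
  # only stops before the last codon indicate pseudogenes.
  sum(aa[-length(aa)] == "*")
}

#' Choose the reading frame of a coding fragment
#'
#' Evaluates the three forward frames (and, optionally, the reverse
#' complement) and returns the one with the fewest internal stop codons,
#' ties broken by lowest frame index with `+` preferred over `-`.
#' `frameshift_suspected` is set when even the best frame retains
#' internal stops, or when the (aligned) input carries a gap run whose
#' length is not a multiple of 3.
#'
#' @param nt Single nucleotide string (gaps allowed; they are stripped
#'   before translation but inspected for frameshift-length runs).
#' @param code Codon map.
#' @param both_strands Also evaluate the reverse complement.
#' @return List with `frame`, `strand`, `peptide`, `n_internal_stops`,
#'   `frameshift_suspected`.
#' @export
best_frame <- function(nt, code = invert_mito_code(), both_strands = FALSE) {
  gaps <- gregexpr("-+", nt)[[1]]
  gap_shift <- !identical(as.integer(gaps), -1L) &&
    any(attr(gaps, "match.length") %% 3L != 0L)
  bare <- gsub("-", "", nt, fixed = TRUE)
  if (nchar(bare) < 30L) stop("need at least 30 nt to call a reading frame")
  strands <- if (both_strands) c("+", "-") else "+"
  best <- NULL
  for (s in strands) {
    for (f in 0:2) {
      pep <- translate_dna(bare, code, frame = f, strand = s)
      k <- .count_internal_stops(pep)
      if (is.null(best) || k < best$n_internal_stops)
        best <- list(frame = f, strand = s, peptide = pep,
                     n_internal_stops = k)
    }
  }
  best$frameshift_suspected <- best$n_internal_stops > 0L || gap_shift
  best
}

#' Reading frame of an alignment
#'
#' Derives a single reading frame for all rows of a nucleotide alignment
#' from its majority-rule consensus (per column, the most frequent
#' unambiguous residue; gap-majority columns become gaps and are
#' stripped). The COI fragments analysed here share one frame, so a
#' consensus call is robust to individual pseudogenes.
#'
#' @param alignment Aligned sequence set.
#' @param code Codon map.
#' @return Integer frame in 0:2.
#' @export
alignment_frame <- function(alignment, code = invert_mito_code()) {
  m <- .seq_matrix(alignment)
  cons <- apply(m, 2, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    if (length(tab) == 0L) "-" else names(tab)[which.max(tab)]
  })
  best_frame(paste(cons, collapse = ""), code)$frame
}

#' Translate every row of a nucleotide alignment
#'
#' All rows are translated in a common frame (by default the consensus
#' frame from [alignment_frame()]); gap triplets become gap characters
#' so that the amino-acid alignment keeps columnar correspondence.
#'
#' @param alignment Aligned nucleotide sequence set.
#' @param code Codon map.
#' @param frame Frame override; `NULL` uses the consensus frame.
#' @return Aligned amino-acid sequence set (gap character `-`).
#' @export
translate_alignment <- function(alignment, code = invert_mito_code(),
                                frame = NULL) {
  if (is.null(frame)) frame <- alignment_frame(alignment, code)
  out <- vapply(alignment, function(nt) {
    codons <- .codons_of(nt, frame)
    aa <- .translate_codons(codons, code)
    aa[codons == "---"] <- "-"
    paste(aa, collapse = "")
  }, character(1))
  names(out) <- names(alignment)
  out
}

#' Detect amino-acid indels against the alignment majority
#'
#' A column is "consensus-residue" when more than half of the rows hold
#' a residue there, and "consensus-gap" when more than half hold a gap.
#' Per row, a maximal gap run across consensus-residue columns is a
#' deletion; a maximal residue run across consensus-gap columns is an
#' insertion. Positions are 1-based amino-acid alignment columns.
#'
#' @param aa_alignment Aligned amino-acid sequence set (>= 4 rows).
#' @return `data.frame` with `sequence_id`, `kind`
#'   (`insertion`/`deletion`), `aa_position` (run start) and
#'   `length_aa`.
#' @export
detect_indels <- function(aa_alignment) {
  if (length(aa_alignment) < 4L)
    stop("indel detection needs at least 4 aligned sequences")
  m <- .seq_matrix(aa_alignment)
  n <- nrow(m)
  gap_frac <- colMeans(m == "-")
  cons_res <- gap_frac < 0.5     # >50% of rows hold a residue
  cons_gap <- gap_frac > 0.5     # >50% of rows hold a gap
  runs_of <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], len = r$lengths[r$values])
  }
  out <- list()
  for (i in seq_len(n)) {
    row_gap <- m[i, ] == "-"
    del <- runs_of(row_gap & cons_res)
    ins <- runs_of(!row_gap & cons_gap)
    if (nrow(del) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = rownames(m)[i], kind = "deletion",
        aa_position = del[, "start"], length_aa = del[, "len"])
    if (nrow(ins) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = rownames(m)[i], kind = "insertion",
        aa_position = ins[, "start"], length_aa = ins[, "len"])
  }
  if (length(out) == 0L)
    return(data.frame(sequence_id = character(0), kind = character(0),
                      aa_position = integer(0), length_aa = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sequence_id, res$aa_position), , drop = FALSE]
}
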