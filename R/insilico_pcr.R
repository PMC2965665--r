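# Degenerate-primer binding-site search and virtual amplification, plus
# the amplification-outcome tallies used to compare primer sets.

#' Built-in COI primer registry
#'
#' The seven I3-M11 primers (JB3, JB4.5, JB5, JB2, JB2s3, JB5GED,
#' JB7GED) with their anchor positions on the *Drosophila yakuba* COI
#' reference, plus the universal Folmer-region pair LCO1490/HCO2198.
#' Sequences are 5'->3' as published.
#'
#' @return `data.frame` with `name`, `sequence`, `orientation`
#'   (`forward`/`reverse`), `anchor_position` and `partition`.
#' @export
primer_registry <- function() {
  data.frame(
    name = c("JB3", "JB4.5", "JB5", "JB2", "JB2s3", "JB5GED", "JB7GED",
             "LCO1490", "HCO2198"),
    sequence = c(
      "TTTTTTGGGCATCCTGAGGTTTAT",
      "TAAAGAAAGAACATAATGAAAATG",
      "AGCACCTAAACTTAAAACATAATGAAAATG",
      "ATGTTTTGATTTTACCWGCWTTYGGTGT",
      "ATGTTTTGATTTTACCWGSWTTTGG",
      "AGCACCTAAACTTAAAACATARTGRAARTG",
      "ATCAGGATAATCCAAATAYTTWCGWGG",
      "GGTCAACAAATCATAAAGATATTGG",
      "TAAACTTCAGGGTGACCAAAAAATCA"),
    orientation = c("forward", "reverse", "reverse", "forward", "forward",
                    "reverse", "reverse", "forward", "reverse"),
    anchor_position = c(2179L, 2597L, 2597L, 2201L, 2201L, 2597L, 2780L,
                        NA, NA),
    partition = c(rep("I3-M11", 7), "Folmer", "Folmer"))
}

#' Construct a primer
#'
#' @param name Primer name.
#' @param sequence IUPAC string, 5'->3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @param anchor_position Optional reference anchor.
#' @return List of class `primer` with a `degeneracy` field (product of
#'   per-base ambiguity cardinalities).
#' @export
primer <- function(name, sequence, orientation,
                   anchor_position = NA_integer_) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  sequence <- toupper(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(ch %in% IUPAC_CHARS))
    stop("non-IUPAC character in primer ", name)
  structure(list(name = name, sequence = sequence,
                 orientation = orientation,
                 anchor_position = anchor_position,
                 degeneracy = as.integer(prod(lengths(IUPAC_SETS[ch])))),
            class = "primer")
}

#' Look up a registry primer by name
#'
#' @param name Name in [primer_registry()].
#' @return A `primer` object.
#' @export
get_primer <- function(name) {
  reg <- primer_registry()
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown primer: ", name)
  primer(reg$name[i], reg$sequence[i], reg$orientation[i],
         reg$anchor_position[i])
}

#' All concrete expansions of a degenerate primer
#'
#' @param p A `primer` object (or IUPAC string).
#' @return Character vector of unambiguous sequences, lexicographically
#'   sorted; its length equals the primer's degeneracy.
#' @export
expand_degenerate <- function(p) {
  s <- if (inherits(p, "primer")) p$sequence else toupper(p)
  sets <- IUPAC_SETS[strsplit(s, "", fixed = TRUE)[[1]]]
  if (anyNA(names(sets))) stop("non-IUPAC character in primer")
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste,
             collapse = ""))
}

#' Find primer binding sites on a template
#'
#' Scans the plus strand of the template for windows matching the
#' primer under IUPAC set-intersection semantics with at most
#' `max_mismatch` mismatches, and requires the 3 template bases facing
#' the primer's 3' end to match exactly (the annealing-critical
#' 3'-anchor). Reverse primers are searched as their reverse complement,
#' so their 3' anchor faces the window start. Coordinates are 0-based
#' half-open.
#'
#' @param p A `primer` object.
#' @param template Nucleotide string (one template).
#' @param max_mismatch Maximum mismatches outside the 3' anchor
#'   (default 2).
#' @return `data.frame` with `start`, `end`, `strand`, `n_mismatches`,
#'   `three_prime_clean`, sorted by position; empty when the template
#'   is shorter than the primer.
#' @export
find_binding_sites <- function(p, template, max_mismatch = 2L) {
  stopifnot(inherits(p, "primer"), max_mismatch >= 0L)
  tmpl <- toupper(template)
  L <- nchar(tmpl); k <- nchar(p$sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_mismatches = integer(0),
                      three_prime_clean = logical(0))
  if (L < k) return(empty)
  query <- if (p$orientation == "forward") p$sequence
           else reverse_complement(p$sequence)
  strand <- if (p$orientation == "forward") "+" else "-"
  # On the plus strand, the primer's 3' end faces the window end for a
  # forward primer and the window start for a reverse primer.
  anchor_idx <- if (p$orientation == "forward") (k - 2L):k else 1:3
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  tc <- strsplit(tmpl, "", fixed = TRUE)[[1]]
  if (!all(tc %in% IUPAC_CHARS)) stop("non-IUPAC character in template")
  # Mismatch profile for every window via shifted vector comparisons.
  n_win <- L - k + 1L
  mism <- integer(n_win)
  anchor_ok <- rep(TRUE, n_win)
  for (off in seq_len(k)) {
    hit <- iupac_match(rep(qc[off], n_win), tc[off:(off + n_win - 1L)])
    mism <- mism + !hit
    if (off %in% anchor_idx) anchor_ok <- anchor_ok & hit
  }
  keep <- which(anchor_ok & mism <= max_mismatch)
  data.frame(start = keep - 1L, end = keep - 1L + k,
             strand = rep(strand, length(keep)),
             n_mismatches = mism[keep],
             three_prime_clean = rep(TRUE, length(keep)))
}

#' Virtual PCR of one template with a primer pair
#'
#' Every combination of a forward and a reverse binding site with the
#' forward site starting before the reverse site ends yields a
#' (primer-inclusive) amplicon, capped at `max_len` as an extension
#' limit. Outcomes are classed the way gel lanes are scored: a product
#' within +/-10% of the expected length and nothing else is an
#' `expected_band`; with extra products, `expected_plus_aspecific`;
#' only off-size products, `aspecific_only`; otherwise `no_product`.
#'
#' @param template Nucleotide string.
#' @param fwd,rev `primer` objects (forward and reverse orientation).
#' @param max_mismatch Mismatch allowance passed to
#'   [find_binding_sites()].
#' @param expected_len Expected amplicon length (primer-inclusive), nt.
#' @param max_len Longest amplifiable product (default 3000 nt).
#' @param tol Relative half-width of the expected-size window
#'   (default 0.10).
#' @return List with `class` and `amplicon_lengths`.
#' @export
amplify <- function(template, fwd, rev, max_mismatch = 2L,
                    expected_len = 430L, max_len = 3000L, tol = 0.10) {
  stopifnot(fwd$orientation == "forward", rev$orientation == "reverse")
  fs <- find_binding_sites(fwd, template, max_mismatch)
  rs <- find_binding_sites(rev, template, max_mismatch)
  lens <- integer(0)
  if (nrow(fs) > 0L && nrow(rs) > 0L) {
    grid <- expand.grid(f = seq_len(nrow(fs)), r = seq_len(nrow(rs)))
    len <- rs$end[grid$r] - fs$start[grid$f]
    lens <- sort(len[fs$start[grid$f] < rs$end[grid$r] & len <= max_len])
  }
  expected <- abs(lens - expected_len) <= tol * expected_len
  cls <- if (length(lens) == 0L) "no_product"
    else if (any(expected) && all(expected)) "expected_band"
    else if (any(expected)) "expected_plus_aspecific"
    else "aspecific_only"
  list(class = cls, amplicon_lengths = lens)
}

#' Tally amplification outcomes across species
#'
#' Reproduces the gel-survey bookkeeping: counts and percentages (one
#' decimal) of species with no product, with any aspecific product, and
#' with amplification success (an expected-size band, with or without
#' aspecific co-products).
#'
#' @param outcomes Character vector of outcome classes (one per
#'   species), or a list of [amplify()] results.
#' @return `data.frame` with `outcome`, `n` and `pct` rows for each
#'   class plus the derived `aspecific_any` and `success` tallies.
#' @export
tally_success <- function(outcomes) {
  if (is.list(outcomes) && !is.data.frame(outcomes))
    outcomes <- vapply(outcomes, `[[`, character(1), "class")
  if (length(outcomes) == 0L) stop("no outcomes to tally")
  valid <- c("expected_band", "expected_plus_aspecific",
             "aspecific_only", "no_product")
  if (!all(outcomes %in% valid))
    stop("unknown outcome class(es): ",
         paste(setdiff(outcomes, valid), collapse = ", "))
  n <- length(outcomes)
  cnt <- vapply(valid, function(v) sum(outcomes == v), integer(1))
  derived <- c(
    aspecific_any = unname(cnt["expected_plus_aspecific"] +
                             cnt["aspecific_only"]),
    success = unname(cnt["expected_band"] +
                       cnt["expected_plus_aspecific"]))
  all_cnt <- c(cnt, derived)
  data.frame(outcome = names(all_cnt), n = unname(all_cnt),
             pct = round(100 * unname(all_cnt) / n, 1),
             n_total = n)
}
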