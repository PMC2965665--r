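# End-to-end sequence quality control: translation checks under the
# invertebrate mitochondrial code, indel detection, a composition-
# outlier screen (stand-in for a similarity search against a reference
# database, which needs no external data), and NJ-tree-based outlier
# flags; plus the sequencing-success and alignment-variability tallies.

#' Default QC configuration
#'
#' `fatal` names the checks whose failure removes a sequence:
#' `stop_codon`, `frameshift`, `composition_outlier` and the joint
#' `tree_outlier` (long branch AND taxonomic outlier). An indel alone
#' is a warning, not fatal -- in-frame indels occur in genuine nematode
#' COI. `gc_margin` is the absolute GC-fraction deviation from the set
#' median that flags a composition outlier; `c_long` the long-branch
#' multiplier.
#'
#' @param gc_margin Absolute GC deviation margin (default 0.15).
#' @param c_long Long-branch multiplier (default 3).
#' @param fatal Character vector of fatal checks.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(gc_margin = 0.15, c_long = 3,
                      fatal = c("stop_codon", "frameshift",
                                "composition_outlier", "tree_outlier")) {
  structure(list(gc_margin = gc_margin, c_long = c_long, fatal = fatal),
            class = "qc_config")
}

#' Composition-outlier screen
#'
#' Flags sequences whose GC fraction deviates from the set median by
#' more than `margin`. This is the package's database-free stand-in for
#' a similarity search against a reference database: contaminants
#' (e.g. bacterial inserts) deviate strongly from the AT-rich nematode
#' mitochondrial composition.
#'
#' @param seqs Sequence set (>= 5 sequences).
#' @param margin Absolute GC deviation margin.
#' @return Named logical vector.
#' @export
composition_outlier <- function(seqs, margin = 0.15) {
  if (length(seqs) < 5L)
    stop("composition screen needs at least 5 sequences")
  gc <- gc_fraction(seqs)
  abs(gc - stats::median(gc, na.rm = TRUE)) > margin
}

#' Run the full quality-control pipeline
#'
#' Pipeline order: (1) per-sequence translation checks in the alignment
#' consensus reading frame (internal stop codons; frameshift-length gap
#' runs), (2) amino-acid indel detection against the alignment
#' majority, (3) composition-outlier screen, (4) K2P distance matrix
#' and NJ tree, (5) long-branch / taxonomic-outlier flags. A sequence
#' fails when any fatal check fires; every removal is logged with its
#' reasons. With fewer than 4 sequences the tree- and indel-based
#' checks are skipped with a warning.
#'
#' @param alignment Aligned nucleotide sequence set.
#' @param records Specimen data frame covering every sequence id.
#' @param config A [qc_config()].
#' @return List of class `qc_report`: `report` (per-sequence check
#'   booleans, `verdict`, `reasons`), `filtered` (passing sequences),
#'   `indels`, `tree` (or NULL).
#' @export
run_qc <- function(alignment, records, config = qc_config()) {
  ids <- names(alignment)
  n <- length(alignment)
  frame <- alignment_frame(alignment)
  checks <- data.frame(
    sequence_id = ids, stop_codon = FALSE, frameshift = FALSE,
    indel = FALSE, composition_outlier = FALSE, long_branch = FALSE,
    taxonomic_outlier = FALSE)
  # (1) translation checks in the shared reading frame
  aa <- translate_alignment(alignment, frame = frame)
  for (i in seq_len(n)) {
    pep <- gsub("-", "", aa[[i]], fixed = TRUE)
    checks$stop_codon[i] <- .count_internal_stops(pep) > 0L
    gaps <- gregexpr("-+", alignment[[i]])[[1]]
    checks$frameshift[i] <- checks$stop_codon[i] ||
      (!identical(as.integer(gaps), -1L) &&
         any(attr(gaps, "match.length") %% 3L != 0L))
  }
  # (2) indels
  indels <- NULL
  if (n >= 4L) {
    indels <- detect_indels(aa)
    checks$indel <- ids %in% indels$sequence_id
  } else {
    warning("fewer than 4 sequences: indel detection skipped")
  }
  # (3) composition screen
  if (n >= 5L)
    checks$composition_outlier <- unname(
      composition_outlier(degap(alignment), config$gc_margin))
  # (4)-(5) tree-based flags
  tree <- NULL
  if (n >= 4L) {
    # Saturated pairs (typically contaminant vs target sequences) are
    # placed at a large proxy distance so the tree screen stays total;
    # see fill_missing_distances().
    m <- fill_missing_distances(distance_matrix(alignment, records))
    tree <- nj_tree(m)
    fl <- flag_tree_outliers(tree, records, config$c_long)
    ord <- match(ids, fl$leaf)
    checks$long_branch <- fl$long_branch[ord]
    checks$taxonomic_outlier <- fl$taxonomic_outlier[ord]
  } else {
    warning("fewer than 4 sequences: tree checks skipped")
  }
  checks$tree_outlier <- checks$long_branch & checks$taxonomic_outlier
  fatal <- intersect(config$fatal, names(checks))
  fatal_m <- as.matrix(checks[, fatal, drop = FALSE])
  fail <- rowSums(fatal_m) > 0
  checks$verdict <- ifelse(fail, "fail", "pass")
  checks$reasons <- apply(fatal_m, 1,
                          function(r) paste(fatal[as.logical(r)],
                                            collapse = ","))
  structure(list(report = checks,
                 filtered = alignment[!fail],
                 indels = indels,
                 tree = tree),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n <- nrow(x$report)
  nf <- sum(x$report$verdict == "fail")
  cat(sprintf("QC report: %d sequences, %d removed\n", n, nf))
  if (nf > 0) {
    bad <- x$report[x$report$verdict == "fail", c("sequence_id", "reasons")]
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  %s: %s\n", bad$sequence_id[i], bad$reasons[i]))
  }
  invisible(x)
}

#' Per-primer and pooled sequencing success
#'
#' Success of a sequencing reaction is a user-supplied boolean (clean
#' chromatogram over at least ~200 bp; trace scoring itself is out of
#' scope). The per-primer rate divides successful reactions by the
#' reactions attempted with that primer; the pooled partition rate
#' divides total successes by total reactions.
#'
#' @param reactions Data frame with columns `primer` and `success`
#'   (logical or 0/1).
#' @param known_primers Character vector of admissible primer names
#'   (default: the built-in registry).
#' @return List with `per_primer` (`primer`, `n_reactions`,
#'   `n_success`, `rate_pct`) and `pooled_rate_pct`, percentages to one
#'   decimal.
#' @export
sequencing_tally <- function(reactions,
                             known_primers = primer_registry()$name) {
  stopifnot(all(c("primer", "success") %in% names(reactions)))
  unknown <- setdiff(unique(reactions$primer), known_primers)
  if (length(unknown) > 0L)
    stop("unknown primer name(s): ", paste(unknown, collapse = ", "))
  succ <- as.logical(reactions$success)
  per <- aggregate(cbind(n_reactions = rep(1L, nrow(reactions)),
                         n_success = as.integer(succ)) ~ primer,
                   data.frame(primer = reactions$primer), sum)
  per$rate_pct <- round(100 * per$n_success / per$n_reactions, 1)
  list(per_primer = per,
       pooled_rate_pct = round(100 * sum(succ) / nrow(reactions), 1))
}

#' Alignment variability report
#'
#' Summarises an alignment the way barcode surveys tabulate partition
#' variability: ungapped sequence-length range, alignment length,
#' fraction of variable nucleotide and amino-acid columns (a column is
#' variable when it holds more than one distinct unambiguous residue),
#' and the K2P distance range per codon position.
#'
#' @param alignment Aligned nucleotide sequence set.
#' @return List with `seq_length_range`, `alignment_length`,
#'   `nt_variable_ratio`, `aa_variable_ratio`, `k2p_range_by_codon`
#'   (3 x 2 matrix; NA for positions with no finite distances).
#' @export
variability_report <- function(alignment) {
  m <- .seq_matrix(alignment)
  var_ratio <- function(mat, ignore) {
    v <- apply(mat, 2, function(col) {
      res <- unique(col[!col %in% ignore])
      length(res) > 1L
    })
    mean(v)
  }
  aa <- translate_alignment(alignment)
  ranges <- t(vapply(1:3, function(p) {
    dm <- distance_matrix(alignment, codon_partition = p)
    d <- dm$d[upper.tri(dm$d)]
    d <- d[is.finite(d)]
    if (length(d) == 0L) c(NA_real_, NA_real_) else range(d)
  }, numeric(2)))
  dimnames(ranges) <- list(paste0("codon_pos_", 1:3), c("min", "max"))
  list(seq_length_range = range(nchar(degap(alignment))),
       alignment_length = ncol(m),
       nt_variable_ratio = var_ratio(m, c("-", setdiff(IUPAC_CHARS,
                                                       c("A", "C", "G", "T")))),
       aa_variable_ratio = var_ratio(.seq_matrix(aa), c("-", "X")),
       k2p_range_by_codon = ranges)
}
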