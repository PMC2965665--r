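# Kimura-2-parameter distances with pairwise deletion, codon-position
# partitioning and taxonomic relation labels.
#
# Pair counting is done for all pairs at once through 0/1 indicator
# matrices and crossproducts (BLAS), so a ~100-sequence alignment costs
# a handful of matrix multiplications rather than n^2 string scans.

#' Transition/transversion counts for one aligned pair
#'
#' Pairwise deletion: sites where either sequence carries a gap or any
#' ambiguity code are skipped. Transitions are A<->G and C<->T; every
#' other differing pair is a transversion.
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @return List with `n_sites`, `n_transitions`, `n_transversions`,
#'   `P` and `Q` (proportions of compared sites).
#' @export
pair_counts <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  diff <- ca != cb
  ts <- sum(diff & ((ca == "A" & cb == "G") | (ca == "G" & cb == "A") |
                    (ca == "C" & cb == "T") | (ca == "T" & cb == "C")))
  tv <- sum(diff) - ts
  list(n_sites = n, n_transitions = ts, n_transversions = tv,
       P = ts / n, Q = tv / n)
}

#' Kimura-2-parameter distance from substitution proportions
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are
#' the transition and transversion proportions among compared sites.
#' Saturated pairs (either logarithm argument non-positive) raise an
#' error carrying `P` and `Q`.
#'
#' @param counts A [pair_counts()] result, or a list with `P` and `Q`.
#' @return Non-negative distance in substitutions per site.
#' @export
k2p <- function(counts) {
  P <- counts$P; Q <- counts$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    cond <- structure(
      class = c("nemabar_saturation", "error", "condition"),
      list(message = sprintf(
             "K2P distance undefined (saturation): P = %.4f, Q = %.4f", P, Q),
           call = sys.call(-1), P = P, Q = Q))
    stop(cond)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

# Pairwise relation labels from specimen records. `species` may contain
# morphospecies labels; same species -> intraspecific, same genus ->
# congeneric, otherwise intergeneric.
.relation_matrix <- function(ids, records) {
  idx <- match(ids, records$sequence_id)
  if (anyNA(idx))
    stop("no specimen record for sequence id(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  sp <- records$species[idx]
  ge <- records$genus[idx]
  same_sp <- outer(sp, sp, "==")
  same_ge <- outer(ge, ge, "==")
  rel <- matrix("intergeneric", length(ids), length(ids),
                dimnames = list(ids, ids))
  rel[same_ge] <- "congeneric"
  rel[same_sp] <- "intraspecific"
  diag(rel) <- NA
  rel
}

#' All-pairs K2P distance matrix
#'
#' Computes transition/transversion counts for every pair with pairwise
#' deletion, converts them through the K2P closed form, and labels each
#' pair `intraspecific`, `congeneric` or `intergeneric` from the
#' specimen records. Saturated or incomparable pairs get `NA` distances
#' and are listed in the `excluded` table rather than clamped.
#'
#' @param alignment Aligned nucleotide sequence set.
#' @param records Specimen data frame (`sequence_id`, `species`,
#'   `genus` used); `NULL` leaves relations unlabelled.
#' @param codon_partition Optional codon position 1, 2 or 3; restricts
#'   counting to that position of the consensus reading frame.
#' @param frame Frame override for the codon partition.
#' @return Object of class `k2p_dist`: list with `taxa`, `d`, `P`, `Q`,
#'   `n_sites`, `relation` matrices, `codon_partition` and `excluded`.
#' @export
distance_matrix <- function(alignment, records = NULL,
                            codon_partition = NULL, frame = NULL) {
  m <- .seq_matrix(alignment)
  ids <- names(alignment)
  if (is.null(ids)) stop("alignment must have sequence ids")
  if (!is.null(codon_partition)) {
    stopifnot(codon_partition %in% 1:3)
    if (is.null(frame)) frame <- alignment_frame(alignment)
    pos <- seq_len(ncol(m))
    keep <- (pos - frame - 1L) %% 3L + 1L == codon_partition & pos > frame
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  X <- lapply(c("A", "C", "G", "T"),
              function(b) (m == b) * 1)
  names(X) <- c("A", "C", "G", "T")
  V <- X$A + X$C + X$G + X$T               # unambiguous-site indicator
  n_sites <- tcrossprod(V)
  match_ct <- Reduce(`+`, lapply(X, tcrossprod))
  ts_ct <- X$A %*% t(X$G) + X$G %*% t(X$A) +
           X$C %*% t(X$T) + X$T %*% t(X$C)
  tv_ct <- n_sites - match_ct - ts_ct
  P <- ts_ct / n_sites
  Q <- tv_ct / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
  d[w1 <= 0 | w2 <= 0] <- NA            # saturation
  d[n_sites == 0] <- NA                 # incomparable
  diag(d) <- 0
  dimnames(d) <- dimnames(P) <- dimnames(Q) <- dimnames(n_sites) <-
    list(ids, ids)
  up <- which(upper.tri(d) & !is.finite(d), arr.ind = TRUE)
  excluded <- data.frame(
    id_a = ids[up[, 1]], id_b = ids[up[, 2]],
    reason = ifelse(n_sites[up] == 0, "no_comparable_sites", "saturation"))
  rel <- if (!is.null(records)) .relation_matrix(ids, records) else NULL
  structure(list(taxa = ids, d = d, P = P, Q = Q, n_sites = n_sites,
                 relation = rel, codon_partition = codon_partition,
                 excluded = excluded),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distance matrix: %d taxa", length(x$taxa)))
  if (!is.null(x$codon_partition))
    cat(sprintf(", codon position %d", x$codon_partition))
  fin <- x$d[upper.tri(x$d)]
  fin <- fin[is.finite(fin)]
  if (length(fin) > 0)
    cat(sprintf("; range %.4f-%.4f", min(fin), max(fin)))
  if (nrow(x$excluded) > 0)
    cat(sprintf("; %d pair(s) excluded", nrow(x$excluded)))
  cat("\n")
  invisible(x)
}

# Long-form upper-triangle extraction used by the gap analysis.
.pair_table <- function(m) {
  stopifnot(inherits(m, "k2p_dist"))
  up <- which(upper.tri(m$d), arr.ind = TRUE)
  data.frame(
    id_a = m$taxa[up[, 1]], id_b = m$taxa[up[, 2]],
    relation = if (is.null(m$relation)) NA_character_ else m$relation[up],
    n_sites = m$n_sites[up], P = m$P[up], Q = m$Q[up], d = m$d[up])
}

#' Long-form pair table of a distance matrix
#'
#' @param m A `k2p_dist` object.
#' @return `data.frame` with `id_a`, `id_b`, `relation`, `n_sites`,
#'   `P`, `Q`, `d` (NA for excluded pairs).
#' @export
pair_table <- function(m) .pair_table(m)

#' Per-taxon distance summaries by relation class
#'
#' Reports, from the labelled pairs: per species the maximum
#' intraspecific distance, per genus the minimum congeneric distance,
#' and the global minimum intergeneric distance, with overall ranges.
#' A class with no pairs is reported absent (`NULL`), never as zero.
#'
#' @param m A `k2p_dist` object with relation labels.
#' @param records Specimen data frame mapping sequence ids to taxonomy.
#' @return List with `per_species`, `per_genus`, `intergeneric_min` and
#'   `ranges`.
#' @export
partition_summaries <- function(m, records) {
  if (is.null(m$relation)) stop("distance matrix has no relation labels")
  pt <- .pair_table(m)
  pt <- pt[is.finite(pt$d), ]
  idx <- match(pt$id_a, records$sequence_id)
  pt$species <- records$species[idx]
  pt$genus <- records$genus[idx]
  out <- list(per_species = NULL, per_genus = NULL,
              intergeneric_min = NULL, ranges = list())
  intra <- pt[pt$relation == "intraspecific", ]
  if (nrow(intra) > 0L) {
    out$per_species <- aggregate(d ~ species, intra, max)
    names(out$per_species)[2] <- "max_intraspecific"
    out$ranges$intraspecific <- range(intra$d)
  }
  cong <- pt[pt$relation == "congeneric", ]
  if (nrow(cong) > 0L) {
    out$per_genus <- aggregate(d ~ genus, cong, min)
    names(out$per_genus)[2] <- "min_congeneric"
    out$ranges$congeneric <- range(cong$d)
  }
  inter <- pt[pt$relation == "intergeneric", ]
  if (nrow(inter) > 0L) {
    out$intergeneric_min <- min(inter$d)
    out$ranges$intergeneric <- range(inter$d)
  }
  out
}

#' Replace missing distances with a large proxy for tree-based QC
#'
#' Saturated or incomparable pairs have no defined K2P distance; they
#' are excluded from distance statistics. Tree construction, however,
#' needs a complete matrix, and a pair beyond the K2P domain is by
#' definition extremely divergent -- exactly the signal the long-branch
#' screen looks for. This helper sets a missing entry to `factor`
#' times the largest finite distance, scaled further by the pair's raw
#' mismatch fraction so that distinct saturated pairs stay distinct (a
#' constant fill would tie large parts of the matrix and degenerate the
#' NJ geometry). The fill can only lengthen the offending leaf's
#' branch. Use it for QC trees only, never for distance summaries.
#'
#' @param m A `k2p_dist` object.
#' @param factor Multiplier on the largest finite distance
#'   (default 1.5).
#' @return A `k2p_dist` object with a complete `d` matrix.
#' @export
fill_missing_distances <- function(m, factor = 1.5) {
  stopifnot(inherits(m, "k2p_dist"))
  d <- m$d
  if (all(is.finite(d))) return(m)
  fin <- d[is.finite(d)]
  proxy <- if (length(fin) > 0 && max(fin) > 0) factor * max(fin) else 1
  miss <- !is.finite(d)
  # scale by the raw mismatch fraction so distinct saturated pairs stay
  # distinct; a constant fill would create massive NJ ties
  pq <- m$P + m$Q
  pq[!is.finite(pq)] <- 1
  d[miss] <- proxy * (1 + pq[miss])
  diag(d) <- 0
  m$d <- d
  m
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param m A `k2p_dist` object (complete; `NA` entries are written as
#'   `-1`, the conventional missing marker).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(m, path) {
  d <- m$d
  d[!is.finite(d)] <- -1
  lines <- c(sprintf("%5d", length(m$taxa)),
             vapply(seq_along(m$taxa), function(i) {
               paste0(formatC(m$taxa[i], width = -12),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
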