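# Barcoding-gap analysis: intra- vs interspecific K2P distance
# distributions, threshold metrics at a fixed cutoff (the 5% rule),
# threshold scanning, and per-relation histograms.

# Finite labelled distances split into intra and pooled inter vectors.
# Congeneric and intergeneric pairs are pooled as "interspecific" for
# the headline fractions; the histogram keeps them separate.
.gap_pairs <- function(m) {
  pt <- pair_table(m)
  if (all(is.na(pt$relation))) stop("distance matrix has no relation labels")
  pt <- pt[is.finite(pt$d) & !is.na(pt$relation), ]
  list(pairs = pt,
       intra = pt$d[pt$relation == "intraspecific"],
       inter = pt$d[pt$relation %in% c("congeneric", "intergeneric")])
}

#' Barcoding-gap metrics at a fixed distance threshold
#'
#' Counts, with strict inequalities, the fraction of intraspecific
#' pairs below `t` and of interspecific (congeneric plus intergeneric)
#' pairs above `t`. Pairs exactly at `t` fall in neither fraction and
#' are reported in `n_boundary`. Species pairs with any interspecific
#' distance below `t` -- the pairs a threshold-based identification
#' would conflate -- are listed in `conflict_pairs`.
#'
#' @param m A `k2p_dist` object with relation labels.
#' @param t Distance threshold (> 0), default 0.05.
#' @param records Optional specimen data frame; when given,
#'   `conflict_pairs` reports species names instead of sequence ids.
#' @return List with `threshold`, `frac_intra_below`,
#'   `frac_inter_above` (NA when a class has no pairs), `n_intra`,
#'   `n_inter`, `n_boundary`, `conflict_pairs`.
#' @export
gap_metrics <- function(m, t = 0.05, records = NULL) {
  stopifnot(t > 0)
  gp <- .gap_pairs(m)
  intra <- gp$intra; inter <- gp$inter
  frac_intra <- if (length(intra) > 0L) mean(intra < t) else NA_real_
  frac_inter <- if (length(inter) > 0L) mean(inter > t) else NA_real_
  n_boundary <- sum(c(intra, inter) == t)
  conf <- gp$pairs[gp$pairs$relation %in% c("congeneric", "intergeneric") &
                     gp$pairs$d < t, c("id_a", "id_b", "relation", "d")]
  if (!is.null(records) && nrow(conf) > 0L) {
    conf$species_a <- records$species[match(conf$id_a, records$sequence_id)]
    conf$species_b <- records$species[match(conf$id_b, records$sequence_id)]
    key <- apply(conf[, c("species_a", "species_b")], 1,
                 function(x) paste(sort(x), collapse = " / "))
    conf <- conf[!duplicated(key), ]
  }
  rownames(conf) <- NULL
  list(threshold = t,
       frac_intra_below = frac_intra, frac_inter_above = frac_inter,
       n_intra = length(intra), n_inter = length(inter),
       n_boundary = n_boundary, conflict_pairs = conf)
}

#' Scan identification thresholds over a grid
#'
#' Evaluates [gap_metrics()] over `t = grid_step, 2 grid_step, ...` up
#' to the largest finite distance, and reports the threshold maximising
#' `min(frac_intra_below, frac_inter_above)`; ties are broken by the
#' smallest threshold, so with fully separated distributions the first
#' grid point above the largest intraspecific distance wins.
#'
#' @param m A `k2p_dist` object with relation labels.
#' @param grid_step Grid spacing (default 0.001).
#' @return List with `table` (`t`, `frac_intra_below`,
#'   `frac_inter_above`, `n_boundary`) and `best_t`.
#' @export
scan_thresholds <- function(m, grid_step = 0.001) {
  stopifnot(grid_step > 0)
  gp <- .gap_pairs(m)
  intra <- gp$intra; inter <- gp$inter
  if (length(intra) == 0L || length(inter) == 0L)
    stop("threshold scan needs both intra- and interspecific pairs")
  # exact decimal grid points (plain seq() accumulates float error,
  # which matters for the strict < / > comparisons)
  grid <- round(grid_step * seq_len(floor(max(c(intra, inter)) /
                                            grid_step + 1e-9)), 10)
  fi <- vapply(grid, function(t) mean(intra < t), numeric(1))
  fo <- vapply(grid, function(t) mean(inter > t), numeric(1))
  nb <- vapply(grid, function(t) sum(c(intra, inter) == t), numeric(1))
  score <- pmin(fi, fo)
  best <- grid[which.max(score)]   # which.max takes the first maximum
  list(table = data.frame(t = grid, frac_intra_below = fi,
                          frac_inter_above = fo, n_boundary = nb),
       best_t = best)
}

#' Per-relation histogram of pairwise distances
#'
#' Half-open bins `[k w, (k+1) w)`; frequencies are relative within
#' each relation class (intraspecific, congeneric, intergeneric), the
#' form in which barcode surveys display the gap. Classes without pairs
#' are omitted.
#'
#' @param m A `k2p_dist` object with relation labels.
#' @param bin_width Bin width (default 0.05).
#' @return `data.frame` with `relation`, `bin_lo`, `bin_hi`,
#'   `rel_freq`.
#' @export
gap_histogram <- function(m, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  pt <- .gap_pairs(m)$pairs
  out <- list()
  for (rel in c("intraspecific", "congeneric", "intergeneric")) {
    d <- pt$d[pt$relation == rel]
    if (length(d) == 0L) next
    bin <- floor(d / bin_width)
    tab <- table(bin)
    out[[rel]] <- data.frame(
      relation = rel,
      bin_lo = as.numeric(names(tab)) * bin_width,
      bin_hi = (as.numeric(names(tab)) + 1) * bin_width,
      rel_freq = as.numeric(tab) / length(d))
  }
  if (length(out) == 0L)
    return(data.frame(relation = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), rel_freq = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
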