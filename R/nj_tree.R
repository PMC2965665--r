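# Neighbor-joining tree construction (Saitou & Nei agglomeration) with
# deterministic tie-breaking, Newick serialization, and the tree-based
# QC flags used to spot pseudogenes and contaminants (long terminal
# branches, taxonomic outliers).

# Internal recursive node: leaf = list(label); internal = list(children,
# lengths). Serialized to full-precision Newick, then parsed by ape into
# a "phylo" object, the container every downstream tree operation uses.

.node_newick <- function(node, digits = 10) {
  if (!is.null(node$label)) return(.quote_label(node$label))
  parts <- vapply(seq_along(node$children), function(i) {
    paste0(.node_newick(node$children[[i]], digits), ":",
           formatC(node$lengths[i], digits = digits, format = "g"))
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

.quote_label <- function(lab) {
  if (grepl("[][ \t(){},;:']", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Neighbor-joining tree from a K2P distance matrix
#'
#' Standard Saitou-Nei agglomeration minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`. Ties in the Q
#' matrix are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest leaf id), so the tree
#' is reproducible regardless of input order. Negative branch lengths
#' are clamped to zero with the deficit moved to the sibling edge, which
#' preserves path lengths. The result is unrooted, serialized with a
#' trifurcating root.
#'
#' @param m A `k2p_dist` object or a complete symmetric numeric matrix
#'   with dimnames.
#' @return An [ape::phylo] object.
#' @export
nj_tree <- function(m) {
  D <- if (inherits(m, "k2p_dist")) m$d else as.matrix(m)
  ids <- rownames(D)
  if (is.null(ids)) stop("distance matrix must carry taxon names")
  if (any(!is.finite(D)))
    stop("distance matrix has missing or saturated entries; ",
         "exclude those taxa before tree building")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- length(ids)
  if (n < 2L) stop("need at least 2 taxa")
  nodes <- lapply(ids, function(id) list(label = id))
  labels <- ids
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  while (length(nodes) > 3L) {
    k <- nrow(D)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1, function(rc) {
        pr <- sort(c(labels[rc[1]], labels[rc[2]]))
        paste(pr, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    bj <- D[i, j] - bi
    b <- clamp_pair(bi, bj)
    new_node <- list(children = list(nodes[[i]], nodes[[j]]),
                     lengths = c(b[1], b[2]))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    nodes <- c(nodes[keep], list(new_node))
    labels <- c(labels[keep], min(labels[c(i, j)]))
    rownames(D) <- colnames(D) <- labels
  }
  if (length(nodes) == 2L) {
    half <- D[1, 2] / 2
    root <- list(children = nodes, lengths = c(half, half))
  } else {
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    root <- list(children = nodes, lengths = pmax(c(a, b, c3), 0))
  }
  # Parse via placeholder labels: arbitrary ids (spaces, parentheses)
  # survive as-is instead of relying on the parser's quoting rules.
  placeholder <- stats::setNames(sprintf("x%d", seq_along(ids)), ids)
  relabel <- function(node) {
    if (!is.null(node$label)) return(list(label = placeholder[[node$label]]))
    node$children <- lapply(node$children, relabel)
    node
  }
  tr <- ape::read.tree(text = paste0(.node_newick(relabel(root)), ";"))
  tr$tip.label <- ids[match(tr$tip.label, placeholder)]
  tr
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with 6 decimal places; labels containing
#' spaces or Newick metacharacters are single-quoted.
#'
#' @param t An [ape::phylo] object.
#' @return Newick string terminated by `;`.
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "phylo"))
  n_tip <- length(t$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) return(.quote_label(t$tip.label[node]))
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      paste0(rec(t$edge[e, 2]), ":",
             sprintf("%.6f", t$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Terminal branch length of every leaf
#'
#' @param t An [ape::phylo] object.
#' @return Named numeric vector, one entry per tip.
#' @export
terminal_branch_lengths <- function(t) {
  n_tip <- length(t$tip.label)
  tip_edge <- match(seq_len(n_tip), t$edge[, 2])
  stats::setNames(t$edge.length[tip_edge], t$tip.label)
}

#' Tree-based QC flags: long branches and taxonomic outliers
#'
#' A leaf is a long branch when its terminal branch exceeds `c_long`
#' times the median terminal branch length. It is additionally a
#' taxonomic outlier when its nearest leaf by path length belongs to a
#' different higher taxon -- the joint signature of the basal,
#' long-branched, taxonomically misplaced sequences that indicate
#' contamination or nuclear pseudogene copies. The two flags are
#' reported separately; requiring both before removal protects genuine
#' but under-sampled lineages.
#'
#' @param t An [ape::phylo] object whose tips are sequence ids.
#' @param records Specimen data frame (`sequence_id`, `higher_taxon`).
#' @param c_long Long-branch multiplier on the median terminal branch
#'   (default 3).
#' @return `data.frame` with `leaf`, `terminal_branch`, `long_branch`,
#'   `taxonomic_outlier`.
#' @export
flag_tree_outliers <- function(t, records, c_long = 3) {
  tb <- terminal_branch_lengths(t)
  idx <- match(names(tb), records$sequence_id)
  if (anyNA(idx))
    stop("no specimen record for leaf/leaves: ",
         paste(names(tb)[is.na(idx)], collapse = ", "))
  taxon <- records$higher_taxon[idx]
  long <- tb > c_long * stats::median(tb)
  pd <- ape::cophenetic.phylo(t)
  diag(pd) <- Inf
  pd <- pd[names(tb), names(tb)]
  nearest <- apply(pd, 1, which.min)
  outlier <- long & (taxon[nearest] != taxon)
  data.frame(leaf = names(tb), terminal_branch = unname(tb),
             long_branch = unname(long),
             taxonomic_outlier = unname(outlier))
}
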