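# Shared fixtures: random sequences, additive trees, and independent
# brute-force oracles used to cross-check the package implementations.

random_dna <- function(len, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random tree with strictly positive branch lengths; its cophenetic
# matrix is additive by construction.
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Site-by-site pair-count oracle, written independently of the
# vectorised implementation in the package.
oracle_pair_counts <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- 0L; ts <- 0L; tv <- 0L
  purines <- c("A", "G")
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T")))
      next
    n <- n + 1L
    if (x != y) {
      if ((x %in% purines) == (y %in% purines)) ts <- ts + 1L
      else tv <- tv + 1L
    }
  }
  list(n_sites = n, n_transitions = ts, n_transversions = tv)
}

# Substitute k random positions with a different base.
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), k)
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

# Unrooted topology equality.
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
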