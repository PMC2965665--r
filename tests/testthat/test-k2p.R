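test_that("pair_counts applies the transition/transversion definitions", {
  pc <- pair_counts("ACGT", "ACGT")
  expect_equal(pc[c("n_sites", "n_transitions", "n_transversions")],
               list(n_sites = 4L, n_transitions = 0L, n_transversions = 0L))
  pc <- pair_counts("AAAA", "GAAA")
  expect_equal(pc$n_transitions, 1L)
  expect_equal(pc$n_transversions, 0L)
  # pairwise deletion: gap and ambiguity sites are skipped
  pc <- pair_counts("A-CT", "AGCA")
  expect_equal(pc$n_sites, 3L)
  expect_equal(pc$n_transitions, 0L)
  expect_equal(pc$n_transversions, 1L)
  pc <- pair_counts("ANCT", "AGCA")
  expect_equal(pc$n_sites, 3L)
  expect_error(pair_counts("----", "AAAA"), "no comparable sites")
  expect_error(pair_counts("AC", "A"), "differ in length")
})

test_that("k2p matches the closed form and detects saturation", {
  expect_equal(k2p(list(P = 0, Q = 0)), 0)
  expect_equal(k2p(list(P = 0.1, Q = 0.05)), 0.170181165, tolerance = 1e-8)
  err <- tryCatch(k2p(list(P = 0.6, Q = 0)), error = identity)
  expect_s3_class(err, "nemabar_saturation")
  expect_equal(err$P, 0.6)
})

test_that("k2p is monotone in P and in Q within its domain", {
  for (q in c(0, 0.05, 0.15)) {
    P <- seq(0, 0.3, by = 0.02)
    d <- vapply(P, function(p) k2p(list(P = p, Q = q)), numeric(1))
    expect_true(all(diff(d) > 0))
  }
  for (p in c(0, 0.1, 0.2)) {
    Q <- seq(0, 0.25, by = 0.02)
    d <- vapply(Q, function(q) k2p(list(P = p, Q = q)), numeric(1))
    expect_true(all(diff(d) > 0))
  }
})

test_that("distance matrix agrees with the site-by-site oracle and ape", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    L <- sample(c(30, 45, 60), 1)
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(random_dna(L), "")[[1]]
      # sprinkle gaps/ambiguities to exercise pairwise deletion
      idx <- sample(L, max(1, L %/% 15))
      s[idx] <- sample(c("-", "N", "R"), length(idx), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("t", seq_len(n))
    m <- distance_matrix(seqs)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      oc <- oracle_pair_counts(seqs[[i]], seqs[[j]])
      expect_equal(m$n_sites[i, j], oc$n_sites)
      P <- oc$n_transitions / oc$n_sites
      Q <- oc$n_transversions / oc$n_sites
      if (1 - 2 * P - Q > 0 && 1 - 2 * Q > 0) {
        expect_equal(m$d[i, j],
                     -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
                     tolerance = 1e-12)
      } else {
        expect_true(is.na(m$d[i, j]))
      }
    }
  }
  # cross-check against ape's K80 distances on gap-free alignments of
  # moderately diverged sequences (within the K2P domain)
  set.seed(32)
  base <- random_dna(300)
  seqs <- c(base, vapply(c(10, 25, 40, 60), function(k) mutate_k(base, k),
                         character(1)))
  names(seqs) <- paste0("t", 1:5)
  m <- distance_matrix(seqs)
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  dape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
  expect_equal(m$d, dape[rownames(m$d), colnames(m$d)], tolerance = 1e-9)
})

test_that("codon partitions isolate positional divergence", {
  code <- invert_mito_code()
  clean <- names(code)[code != "*"]
  set.seed(33)
  a <- paste(sample(clean, 50, replace = TRUE), collapse = "")
  # diverge only third positions, avoiding stop creation
  ch <- strsplit(a, "")[[1]]
  idx3 <- seq(3, length(ch), by = 3)
  flip <- idx3[seq(1, length(idx3), by = 4)]
  ch[flip] <- c(A = "G", G = "A", C = "T", T = "C")[ch[flip]]
  b <- paste(ch, collapse = "")
  aln <- c(x = a, y = b)
  expect_equal(distance_matrix(aln, codon_partition = 1, frame = 0)$d["x", "y"], 0)
  expect_equal(distance_matrix(aln, codon_partition = 2, frame = 0)$d["x", "y"], 0)
  expect_gt(distance_matrix(aln, codon_partition = 3, frame = 0)$d["x", "y"], 0)
})

test_that("relation labels and partition summaries follow the taxonomy", {
  recs <- data.frame(
    voucher = paste0("v", 1:5),
    species = c("G1 sp1", "G1 sp1", "G1 sp2", "G2 sp1", "G2 sp1"),
    genus = c("G1", "G1", "G1", "G2", "G2"),
    higher_taxon = "O1", location = "x",
    sequence_id = paste0("s", 1:5))
  set.seed(34)
  base <- random_dna(120)
  seqs <- c(s1 = base, s2 = mutate_k(base, 2), s3 = mutate_k(base, 12),
            s4 = mutate_k(base, 30), s5 = mutate_k(base, 31))
  m <- distance_matrix(seqs, recs)
  expect_identical(m$relation["s1", "s2"], "intraspecific")
  expect_identical(m$relation["s1", "s3"], "congeneric")
  expect_identical(m$relation["s1", "s4"], "intergeneric")
  ps <- partition_summaries(m, recs)
  expect_identical(ps$per_species$species[1], "G1 sp1")
  expect_true(is.numeric(ps$intergeneric_min))
  # identical conspecific sequences give an all-zero intra summary
  m0 <- distance_matrix(c(s1 = base, s2 = base), recs[1:2, ])
  ps0 <- partition_summaries(m0, recs)
  expect_equal(ps0$per_species$max_intraspecific, 0)
  expect_null(ps0$per_genus)     # absent class reported absent, not zero
  expect_null(ps0$intergeneric_min)
})

test_that("k2p equals Jukes-Cantor when transitions:transversions = 1:2", {
  for (k in c(3, 9, 15)) {
    n <- 300
    P <- k / n; Q <- 2 * k / n
    d_k2p <- k2p(list(P = P, Q = Q))
    p <- P + Q
    d_jc <- -0.75 * log(1 - 4 * p / 3)
    expect_equal(d_k2p, d_jc, tolerance = 1e-9)
  }
})
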