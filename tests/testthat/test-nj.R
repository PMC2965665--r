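test_that("small trees follow the closed-form branch lengths", {
  D2 <- matrix(c(0, .2, .2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
  t2 <- nj_tree(D2)
  expect_identical(to_newick(t2), "(A:0.100000,B:0.100000);")

  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(D3)
  tb <- terminal_branch_lengths(t3)
  expect_equal(tb[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  # additive 4-taxon case: topology AB|CD, internal edge 1,
  # leaf edges 1,2,3,4
  D4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(D4)
  expect_equal(terminal_branch_lengths(t4)[LETTERS[1:4]],
               c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(ape::cophenetic.phylo(t4)[LETTERS[1:4], LETTERS[1:4]], D4)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_true(same_topology(t4, ref))
})

test_that("nj recovers random additive trees exactly", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    fix <- random_additive_matrix(n)
    tr <- nj_tree(fix$D)
    expect_true(same_topology(tr, fix$tree))
    pd <- ape::cophenetic.phylo(tr)
    expect_equal(pd[rownames(fix$D), colnames(fix$D)], fix$D,
                 tolerance = 1e-9)
  }
})

test_that("nj topology matches ape's implementation on generic matrices", {
  set.seed(42)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    pts <- matrix(stats::runif(n * 3), n)
    D <- as.matrix(stats::dist(pts))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_true(same_topology(mine, ref))
  }
})

test_that("nj output is invariant under taxon reordering", {
  set.seed(43)
  fix <- random_additive_matrix(8)
  t1 <- nj_tree(fix$D)
  perm <- sample(nrow(fix$D))
  t2 <- nj_tree(fix$D[perm, perm])
  expect_true(same_topology(t1, t2))
  ids <- rownames(fix$D)
  expect_equal(ape::cophenetic.phylo(t1)[ids, ids],
               ape::cophenetic.phylo(t2)[ids, ids], tolerance = 1e-9)
})

test_that("nj rejects incomplete or asymmetric matrices", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  Dna <- D; Dna[1, 2] <- NA
  expect_error(nj_tree(Dna), "missing")
  Dasym <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = dimnames(D))
  expect_error(nj_tree(Dasym), "symmetric")
})

test_that("newick serialization round-trips and quotes awkward labels", {
  D4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(D4)
  back <- ape::read.tree(text = to_newick(t4))
  expect_true(same_topology(t4, back))
  expect_equal(ape::cophenetic.phylo(back)[LETTERS[1:4], LETTERS[1:4]],
               D4, tolerance = 1e-6)

  dimnames(D4) <- rep(list(c("sp one", "sp two", "sp(3)", "plain")), 2)
  nwk <- to_newick(nj_tree(D4))
  expect_match(nwk, "'sp one'", fixed = TRUE)
  back <- ape::read.tree(text = nwk)
  # ape's parser keeps the surrounding quotes; strip them to compare
  expect_setequal(gsub("^'|'$", "", back$tip.label),
                  c("sp one", "sp two", "sp(3)", "plain"))
})

test_that("tree outlier flags need both branch length and taxonomy evidence", {
  # star-like tree with equal terminal branches: nothing flagged
  recs <- data.frame(voucher = paste0("v", 1:6),
                     species = paste0("S", 1:6), genus = paste0("G", 1:6),
                     higher_taxon = c(rep("O1", 5), "O2"),
                     location = "x", sequence_id = paste0("s", 1:6))
  star <- ape::read.tree(text =
    "(s1:0.1,s2:0.1,s3:0.1,s4:0.1,s5:0.1,s6:0.1);")
  fl <- flag_tree_outliers(star, recs)
  expect_false(any(fl$long_branch))
  expect_false(any(fl$taxonomic_outlier))

  # one leaf 10x median and nearest neighbour from another order
  tr <- ape::read.tree(text =
    "((s1:0.1,s2:0.1):0.05,(s3:0.1,s4:0.1):0.05,(s5:0.1,s6:1.0):0.05);")
  recs2 <- recs
  recs2$higher_taxon <- c("O1", "O1", "O1", "O1", "O2", "O1")
  fl <- flag_tree_outliers(tr, recs2)
  expect_identical(fl$leaf[fl$long_branch], "s6")
  expect_identical(fl$leaf[fl$taxonomic_outlier], "s6")
  # same tree but every leaf from one order: long branch only
  recs3 <- recs
  recs3$higher_taxon <- "O1"
  fl2 <- flag_tree_outliers(tr, recs3)
  expect_identical(fl2$leaf[fl2$long_branch], "s6")
  expect_false(any(fl2$taxonomic_outlier))
  expect_error(flag_tree_outliers(tr, recs[1:3, ]), "no specimen record")
})

test_that("an injected contaminant surfaces as a long branch in the QC tree", {
  hits <- 0L
  for (s in 101:120) {
    cfg <- sim_config(seed = s, n_genera = 8,
                      species_per_genus = c(2, 1), p_numt = 0,
                      p_contaminant = 0)
    ds <- make_dataset(cfg)
    # swap one specimen's sequence for a GC-rich unrelated sequence
    victim <- sample(length(ds$sequences), 1)
    ds$sequences[victim] <- root_sequence(cfg, cfg$contaminant_base_freqs)
    cont <- names(ds$sequences)[victim]
    m <- fill_missing_distances(distance_matrix(ds$sequences, ds$records))
    fl <- flag_tree_outliers(nj_tree(m), ds$records)
    if (fl$long_branch[fl$leaf == cont]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
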