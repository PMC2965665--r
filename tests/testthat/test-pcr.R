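test_that("degenerate expansion enumerates the ambiguity product", {
  expect_identical(expand_degenerate("ACG"), "ACG")
  expect_identical(length(expand_degenerate("NN")), 16L)
  jb2 <- get_primer("JB2")
  ex <- expand_degenerate(jb2)
  expect_identical(length(ex), 8L)
  expect_identical(length(ex), jb2$degeneracy)
  expect_false(is.unsorted(ex))
  expect_true(all(!grepl("[^ACGT]", ex)))
})

test_that("registry carries all survey primers with their orientations", {
  reg <- primer_registry()
  expect_setequal(
    reg$name[reg$partition == "I3-M11"],
    c("JB3", "JB4.5", "JB5", "JB2", "JB2s3", "JB5GED", "JB7GED"))
  expect_identical(get_primer("JB3")$sequence,
                   "TTTTTTGGGCATCCTGAGGTTTAT")
  expect_identical(get_primer("JB5GED")$sequence,
                   "AGCACCTAAACTTAAAACATARTGRAARTG")
  expect_identical(get_primer("LCO1490")$orientation, "forward")
  expect_error(get_primer("nope"), "unknown primer")
})

test_that("binding-site search honours mismatch budget and 3' anchor", {
  jb3 <- get_primer("JB3")
  set.seed(61)
  left <- random_dna(100); right <- random_dna(80)
  tmpl <- paste0(left, jb3$sequence, right)
  hits <- find_binding_sites(jb3, tmpl)
  expect_identical(hits$start, 100L)
  expect_identical(hits$end, 100L + nchar(jb3$sequence))
  expect_identical(hits$n_mismatches, 0L)

  # a substitution at the primer's 3'-terminal base kills the site
  broken <- tmpl
  pos <- 100L + nchar(jb3$sequence)   # 1-based position of last base
  substr(broken, pos, pos) <- if (substr(broken, pos, pos) == "A") "C" else "A"
  expect_identical(nrow(find_binding_sites(jb3, broken)), 0L)

  # an internal substitution is tolerated within the budget
  internal <- tmpl
  substr(internal, 105, 105) <-
    if (substr(internal, 105, 105) == "A") "C" else "A"
  expect_identical(find_binding_sites(jb3, internal)$n_mismatches, 1L)
  expect_identical(nrow(find_binding_sites(jb3, internal,
                                           max_mismatch = 0L)), 0L)

  # two planted forward sites come back in coordinate order
  tmpl2 <- paste0(left, jb3$sequence, right, jb3$sequence, right)
  hits2 <- find_binding_sites(jb3, tmpl2)
  expect_identical(hits2$start, c(100L, 204L))

  # template shorter than the primer: empty result, not an error
  expect_identical(nrow(find_binding_sites(jb3, "ACGT")), 0L)
})

test_that("search equals the expand-and-exact-match oracle", {
  set.seed(62)
  for (rep in 1:8) {
    p <- primer("deg", paste0(random_dna(10), "WSY", random_dna(8)),
                "forward")
    expect_lte(p$degeneracy, 16L)
    tmpl <- random_dna(sample(500:2000, 1))
    # plant two expansions
    ex <- expand_degenerate(p)
    at <- sort(sample(seq_len(nchar(tmpl) - 50), 2))
    if (diff(at) > 25) {
      for (a in at) {
        pick <- sample(ex, 1)
        substr(tmpl, a, a + nchar(pick) - 1L) <- pick
      }
    }
    mine <- find_binding_sites(p, tmpl, max_mismatch = 0L)$start
    oracle <- sort(unique(unlist(lapply(ex, function(e) {
      g <- gregexpr(e, tmpl, fixed = TRUE)[[1]]
      if (identical(as.integer(g), -1L)) integer(0) else as.integer(g) - 1L
    }))))
    expect_identical(mine, oracle)
  }
})

test_that("virtual amplification classes follow the gel-scoring rules", {
  jb3 <- get_primer("JB3"); jb5 <- get_primer("JB5")
  set.seed(63)
  insert <- random_dna(360)
  tmpl <- paste0(random_dna(50), jb3$sequence, insert,
                 reverse_complement(jb5$sequence), random_dna(40))
  elen <- nchar(jb3$sequence) + 360 + nchar(jb5$sequence)
  out <- amplify(tmpl, jb3, jb5, expected_len = elen)
  expect_identical(out$class, "expected_band")
  expect_equal(out$amplicon_lengths, elen)

  # no reverse site -> no product
  out <- amplify(paste0(random_dna(50), jb3$sequence, insert),
                 jb3, jb5, expected_len = elen)
  expect_identical(out$class, "no_product")

  # an extra downstream reverse site adds a spurious product
  tmpl2 <- paste0(tmpl, random_dna(100),
                  reverse_complement(jb5$sequence), random_dna(20))
  out <- amplify(tmpl2, jb3, jb5, expected_len = elen)
  expect_identical(out$class, "expected_plus_aspecific")
  expect_identical(length(out$amplicon_lengths), 2L)

  # off-size product only
  short <- paste0(random_dna(20), jb3$sequence, random_dna(60),
                  reverse_complement(jb5$sequence), random_dna(20))
  out <- amplify(short, jb3, jb5, expected_len = elen)
  expect_identical(out$class, "aspecific_only")
})

test_that("amplification is strand-consistent", {
  jb3 <- get_primer("JB3"); jb5 <- get_primer("JB5")
  set.seed(64)
  tmpl <- paste0(random_dna(30), jb3$sequence, random_dna(360),
                 reverse_complement(jb5$sequence), random_dna(30))
  fwd_view <- amplify(tmpl, jb3, jb5, expected_len = 414)
  # reverse-complement the template and swap primer roles
  swap_f <- primer("JB5f", get_primer("JB5")$sequence, "forward")
  swap_r <- primer("JB3r", get_primer("JB3")$sequence, "reverse")
  rev_view <- amplify(reverse_complement(tmpl), swap_f, swap_r,
                      expected_len = 414)
  expect_identical(fwd_view$amplicon_lengths, rev_view$amplicon_lengths)
})

test_that("success tallies reproduce printed survey percentages", {
  out <- c(rep("no_product", 3), rep("expected_band", 31),
           rep("expected_plus_aspecific", 7))
  tt <- tally_success(out)
  expect_equal(tt$pct[tt$outcome == "no_product"], 7.3)
  expect_equal(tt$n[tt$outcome == "success"], 38L)

  tt13 <- tally_success(c(rep("no_product", 13), rep("expected_band", 28)))
  expect_equal(tt13$pct[tt13$outcome == "no_product"], 31.7)

  tt_all <- tally_success(rep("expected_band", 10))
  expect_equal(tt_all$pct[tt_all$outcome == "success"], 100.0)
  expect_equal(tt_all$pct[tt_all$outcome == "no_product"], 0.0)
  # percentages recompute exactly from counts
  expect_equal(tt$pct, round(100 * tt$n / tt$n_total[1], 1))
  expect_error(tally_success(character(0)), "no outcomes")
  expect_error(tally_success("banana"), "unknown outcome")
})
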