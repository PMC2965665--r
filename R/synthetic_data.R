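# Seeded generator of labelled COI-like datasets with the statistical
# structure of a marine-nematode barcode survey: AT-rich protein-coding
# fragments, strong codon-position rate heterogeneity, intraspecific
# divergences well below the interspecific range, and injected nuclear
# pseudogene (numt) and contaminant sequences with ground-truth flags.

#' Simulation configuration
#'
#' Defaults emulate the survey the analysis is built for: 33 genera /
#' 41 species / 102 specimens, a 393-nt I3-M11-like fragment, AT-rich
#' composition (A .27, C .12, G .19, T .42), transition/transversion
#' rate ratio kappa = 4, codon-position rate multipliers (1, 0.3, 8),
#' intraspecific expected K2P divergence 0.005-0.03, congeneric
#' 0.10-0.26, inter-genus divergence floor 0.12, and injection rates of
#' 10% numts and 5% contaminants.
#'
#' @param seed Integer RNG seed.
#' @param n_genera Number of genera.
#' @param species_per_genus Integer vector (recycled) of species counts
#'   per genus; the default gives 41 species over 33 genera.
#' @param specimens_per_species Integer vector (recycled) of specimen
#'   counts per species; the default gives 102 specimens.
#' @param fragment_length Fragment length in nt (multiple of 3).
#' @param base_freqs Target composition, named A/C/G/T, summing to 1.
#' @param kappa Transition/transversion rate ratio.
#' @param codon_rate_multipliers Relative rates of codon positions
#'   1, 2, 3.
#' @param intra_div,congeneric_div Ranges of expected pairwise K2P
#'   divergence within species and between congeneric species.
#' @param intergeneric_div_min Minimum expected pairwise divergence
#'   between genus ancestors.
#' @param intergeneric_div_max Upper bound of the genus-depth draw.
#' @param p_numt,p_contaminant Per-specimen injection probabilities.
#' @param numt_rate_factor Rate of numt evolution relative to the
#'   mitochondrial rate.
#' @param contaminant_base_freqs Composition of injected contaminants
#'   (GC-shifted).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genera = 33L,
                       species_per_genus = c(rep(2L, 8L), rep(1L, 25L)),
                       specimens_per_species = c(rep(3L, 20L), rep(2L, 21L)),
                       fragment_length = 393L,
                       base_freqs = c(A = 0.27, C = 0.12, G = 0.19, T = 0.42),
                       kappa = 4,
                       codon_rate_multipliers = c(1.0, 0.3, 8.0),
                       intra_div = c(0.005, 0.03),
                       congeneric_div = c(0.10, 0.26),
                       intergeneric_div_min = 0.12,
                       intergeneric_div_max = 0.50,
                       p_numt = 0.10,
                       p_contaminant = 0.05,
                       numt_rate_factor = 0.3,
                       contaminant_base_freqs =
                         c(A = 0.22, C = 0.28, G = 0.27, T = 0.23)) {
  stopifnot(fragment_length %% 3L == 0L,
            abs(sum(base_freqs) - 1) < 1e-9,
            intra_div[1] <= intra_div[2],
            congeneric_div[1] <= congeneric_div[2],
            intergeneric_div_min <= intergeneric_div_max,
            p_numt >= 0, p_contaminant >= 0, p_numt + p_contaminant <= 1)
  if (intra_div[2] >= congeneric_div[1])
    stop("infeasible divergence ordering: intraspecific range must lie ",
         "below the congeneric range")
  structure(as.list(environment()), class = "sim_config")
}

.stop_codons <- c("TAA", "TAG")

# Draw n codons with iid per-base composition, rejecting stop codons.
.draw_codons <- function(n, freqs) {
  bases <- names(freqs)
  draw <- function(k) {
    m <- matrix(sample(bases, 3L * k, replace = TRUE, prob = freqs),
                ncol = 3L)
    paste0(m[, 1], m[, 2], m[, 3])
  }
  out <- draw(n)
  repeat {
    bad <- out %in% .stop_codons
    if (!any(bad)) break
    out[bad] <- draw(sum(bad))
  }
  out
}

#' Random ancestral coding fragment
#'
#' Codons are drawn with independent per-base target composition; the
#' two table-5 stop codons (TAA, TAG) are rejected so the fragment is
#' an open reading frame in frame 0. Reproducible given the RNG state.
#'
#' @param cfg A [sim_config()].
#' @param base_freqs Composition override.
#' @return Single nucleotide string of `cfg$fragment_length` nt.
#' @export
root_sequence <- function(cfg, base_freqs = cfg$base_freqs) {
  paste(.draw_codons(cfg$fragment_length %/% 3L, base_freqs),
        collapse = "")
}

# K2P substitution probabilities at branch length d (expected
# substitutions/site): with transition rate a and per-target
# transversion rate b, d = (a + 2b) t and
#   P(transition)        = 1/4 + 1/4 e^{-4bt} - 1/2 e^{-2(a+b)t}
#   P(each transversion) = 1/4 - 1/4 e^{-4bt}
.k2p_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv_each <- 0.25 - 0.25 * e1
  cbind(ts = ts, tv = 2 * tv_each)
}

#' Evolve a coding sequence to a target K2P divergence
#'
#' Simulates the Kimura-2-parameter process exactly via its closed-form
#' site transition probabilities: each site independently undergoes a
#' transition, a transversion (uniform over the two targets) or no
#' change, with probabilities at branch length `target_div` scaled by
#' the codon-position rate multiplier of the site (normalised to mean
#' 1). Codons that would become stops (TAA/TAG in frame 0) are reverted
#' to the parent codon, keeping the fragment coding.
#'
#' @param seq Parent nucleotide string (frame-0 coding, length a
#'   multiple of 3).
#' @param target_div Expected K2P distance to the parent
#'   (substitutions/site).
#' @param cfg A [sim_config()].
#' @param rate_factor Overall rate scaling (used for slow numt
#'   evolution).
#' @return Child nucleotide string.
#' @export
evolve_seq <- function(seq, target_div, cfg, rate_factor = 1) {
  stopifnot(target_div >= 0)
  if (target_div * rate_factor == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  r <- cfg$codon_rate_multipliers
  site_mult <- r[(seq_len(L) - 1L) %% 3L + 1L] / mean(r)
  d_site <- target_div * rate_factor * site_mult
  pr <- .k2p_probs(d_site, cfg$kappa)
  u <- stats::runif(L)
  do_ts <- u < pr[, "ts"]
  do_tv <- !do_ts & u < pr[, "ts"] + pr[, "tv"]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  new <- ch
  new[do_ts] <- ts_map[ch[do_ts]]
  if (any(do_tv)) {
    pick <- stats::runif(sum(do_tv)) < 0.5
    new[do_tv] <- mapply(function(b, first) tv_map[[b]][1 + !first],
                         ch[do_tv], pick)
  }
  # Revert stop-creating changes so the lineage stays coding.
  cod_start <- seq(1L, L, by = 3L)
  codons <- paste0(new[cod_start], new[cod_start + 1L], new[cod_start + 2L])
  bad <- which(codons %in% .stop_codons)
  for (b in bad) {
    idx <- (3L * (b - 1L) + 1L):(3L * b)
    new[idx] <- ch[idx]
  }
  paste(new, collapse = "")
}

.inject_stop <- function(seq, n_stops = 1L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_cod <- length(ch) %/% 3L
  # internal codons only (not first, not last)
  pos <- sample(2:(n_cod - 1L), n_stops)
  for (p in pos) {
    idx <- (3L * (p - 1L) + 1L):(3L * p)
    ch[idx] <- strsplit(sample(.stop_codons, 1L), "", fixed = TRUE)[[1]]
  }
  paste(ch, collapse = "")
}

# Deletion of `len` nt (len %% 3 != 0) at a random internal position;
# returns the gapped (aligned) form, same length as input.
.inject_frameshift <- function(seq, len) {
  L <- nchar(seq)
  at <- sample(seq(30L, L - 30L - len), 1L)
  paste0(substr(seq, 1L, at - 1L), strrep("-", len),
         substr(seq, at + len, L))
}

#' Generate a labelled synthetic barcode dataset
#'
#' Builds a star-like taxonomy: genus ancestors evolve independently
#' from a common root (depth half of a uniform draw in
#' `[intergeneric_div_min, intergeneric_div_max]`), species ancestors
#' from their genus root (half of a congeneric-range draw), and
#' specimens from their species ancestor (half of an intraspecific-range
#' draw), so expected pairwise divergences land in the configured
#' ranges. A fraction of specimens is replaced by numts (slowly evolved
#' copies carrying one or two internal stop codons, or a 1-2 nt
#' frameshift deletion) or by GC-rich contaminant sequences; ground
#' truth is recorded per specimen.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_dataset` with `sequences` (aligned set;
#'   frameshift numts carry gap characters), `records` (specimen table
#'   with `is_numt`, `is_contaminant`, `numt_kind`, `source_species`),
#'   and `manifest` (config plus realized divergence summary).
#' @export
make_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_sp_per_genus <- rep_len(cfg$species_per_genus, cfg$n_genera)
  n_species <- sum(n_sp_per_genus)
  n_per_sp <- rep_len(cfg$specimens_per_species, n_species)
  ancestor <- root_sequence(cfg)
  seqs <- character(0); ids <- character(0)
  rec <- list()
  sp_counter <- 0L
  taxon_orders <- paste0("Order_", LETTERS[1:4])
  for (g in seq_len(cfg$n_genera)) {
    genus <- sprintf("Genus%02d", g)
    ho <- taxon_orders[(g - 1L) %% length(taxon_orders) + 1L]
    depth_g <- stats::runif(1, cfg$intergeneric_div_min,
                            cfg$intergeneric_div_max) / 2
    genus_root <- evolve_seq(ancestor, depth_g, cfg)
    for (s in seq_len(n_sp_per_genus[g])) {
      sp_counter <- sp_counter + 1L
      species <- sprintf("%s sp%d", genus, s)
      depth_s <- stats::runif(1, cfg$congeneric_div[1],
                              cfg$congeneric_div[2]) / 2
      sp_root <- evolve_seq(genus_root, depth_s, cfg)
      for (k in seq_len(n_per_sp[sp_counter])) {
        depth_i <- stats::runif(1, cfg$intra_div[1], cfg$intra_div[2]) / 2
        sid <- sprintf("g%02ds%d_%d", g, s, k)
        seqs <- c(seqs, evolve_seq(sp_root, depth_i, cfg))
        ids <- c(ids, sid)
        rec[[length(rec) + 1L]] <- data.frame(
          voucher = paste0("V", sid), species = species, genus = genus,
          higher_taxon = ho, location = "synthetic", sequence_id = sid,
          is_numt = FALSE, is_contaminant = FALSE,
          numt_kind = NA_character_, source_species = species)
      }
    }
  }
  records <- do.call(rbind, rec)
  names(seqs) <- ids
  # Artifact injection: replace each specimen's sequence with a numt or
  # a contaminant according to the configured rates.
  u <- stats::runif(length(seqs))
  numt_idx <- which(u < cfg$p_numt)
  cont_idx <- which(u >= cfg$p_numt & u < cfg$p_numt + cfg$p_contaminant)
  for (i in numt_idx) {
    base <- evolve_seq(seqs[[i]], stats::runif(1, 0.005, 0.02), cfg,
                       rate_factor = cfg$numt_rate_factor)
    kind <- sample(c("stop", "frameshift"), 1L)
    seqs[i] <- if (kind == "stop") .inject_stop(base, sample(1:2, 1L))
               else .inject_frameshift(base, sample(c(1L, 2L), 1L))
    records$is_numt[i] <- TRUE
    records$numt_kind[i] <- kind
  }
  for (i in cont_idx) {
    seqs[i] <- root_sequence(cfg, cfg$contaminant_base_freqs)
    records$is_contaminant[i] <- TRUE
    records$source_species[i] <- "non-target organism"
  }
  clean <- !(records$is_numt | records$is_contaminant)
  manifest <- list(config = unclass(cfg),
                   n_species = n_species,
                   n_specimens = length(seqs),
                   n_numts = length(numt_idx),
                   n_contaminants = length(cont_idx))
  structure(list(sequences = seqs, records = records,
                 manifest = manifest, clean = clean),
            class = "sim_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits aligned FASTA, the specimen TSV, a truth TSV and (when
#' jsonlite is installed) a manifest JSON.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$sequences, file.path(dir, "sequences.fasta"))
  write_specimen_table(ds$records[SPECIMEN_COLUMNS],
                       file.path(dir, "specimens.tsv"))
  utils::write.table(
    ds$records[c("sequence_id", "is_numt", "is_contaminant",
                 "numt_kind", "source_species")],
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
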