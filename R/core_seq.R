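# Sequence sets, FASTA and specimen-table I/O, base composition.
#
# A sequence set is a named character vector: names are record ids
# (unique), values are uppercase IUPAC residue strings; '-' is legal only
# in aligned sets. Record descriptions (text after the first whitespace
# in a FASTA header) travel in the "descriptions" attribute.

.validate_residues <- function(res, id, line = NA, allow_gap = FALSE) {
  alphabet <- if (allow_gap) c(IUPAC_CHARS, "-") else IUPAC_CHARS
  ch <- unique(strsplit(res, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, alphabet)
  if (length(bad) > 0L) {
    where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
    stop(sprintf("illegal character(s) %s in record '%s'%s",
                 paste(sQuote(bad), collapse = ", "), id, where))
  }
  invisible(res)
}

#' Build a sequence set from ids and residue strings
#'
#' @param residues Character vector of nucleotide strings (any case;
#'   `U` is folded to `T`).
#' @param ids Character vector of unique record ids.
#' @param descriptions Optional character vector of free-text
#'   descriptions.
#' @param aligned Logical; permit `-` gap characters.
#' @return Named character vector of validated, uppercase sequences.
#' @export
seq_set <- function(residues, ids, descriptions = NULL, aligned = FALSE) {
  stopifnot(length(residues) == length(ids))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  res <- chartr("u", "U", toupper(residues))
  res <- chartr("U", "T", res)
  if (any(!nzchar(res))) stop("empty residue string")
  for (i in seq_along(res)) .validate_residues(res[i], ids[i], allow_gap = aligned)
  names(res) <- ids
  if (!is.null(descriptions)) attr(res, "descriptions") <- descriptions
  res
}

#' Read a FASTA file into a sequence set
#'
#' Multi-line records are joined, residues are uppercased and `U` is
#' folded to `T`. Parse failures (text before the first header, illegal
#' characters, duplicate ids) name the offending record and line.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; permit `-` gap characters in records.
#' @return A sequence set (named character vector) with a
#'   `"descriptions"` attribute.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("no FASTA records in ", path)
  first_hdr <- which(hdr)[1]
  pre <- lines[seq_len(first_hdr - 1L)]
  if (any(nzchar(trimws(pre))))
    stop(sprintf("malformed FASTA: sequence data before first header (line %d)",
                 which(nzchar(trimws(pre)))[1]))
  rec_idx <- cumsum(hdr)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  for (r in seq_len(max(rec_idx))) {
    block <- which(rec_idx == r)
    header <- sub("^>", "", lines[block[1]])
    id <- sub("\\s.*$", "", header)
    if (!nzchar(id))
      stop(sprintf("malformed FASTA header at line %d: empty id", block[1]))
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    body_lines <- block[-1]
    body <- toupper(paste(gsub("\\s", "", lines[body_lines]), collapse = ""))
    body <- chartr("U", "T", body)
    if (!nzchar(body))
      stop(sprintf("empty record '%s' (line %d)", id, block[1]))
    if (id %in% ids)
      stop(sprintf("duplicate sequence id '%s' (line %d)", id, block[1]))
    .validate_residues(body, id, line = block[1], allow_gap = aligned)
    ids <- c(ids, id); descs <- c(descs, desc); seqs <- c(seqs, body)
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- descs
  seqs
}

#' Write a sequence set to FASTA
#'
#' Residues are wrapped at 60 columns; a description attribute, if
#' present and non-empty, is appended to the header after a space.
#'
#' @param seqs A sequence set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  descs <- attr(seqs, "descriptions")
  out <- character(0)
  for (i in seq_along(seqs)) {
    hdr <- paste0(">", names(seqs)[i])
    if (!is.null(descs) && nzchar(descs[i])) hdr <- paste(hdr, descs[i])
    body <- seqs[[i]]
    starts <- seq(1L, nchar(body), by = 60L)
    out <- c(out, hdr, substring(body, starts, pmin(starts + 59L, nchar(body))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Pooled base composition of a sequence set
#'
#' Proportions of A, C, G and T over all sequences pooled; ambiguity
#' codes and gaps are excluded from the denominator.
#'
#' @param seqs A sequence set.
#' @return List with `frac_A`, `frac_C`, `frac_G`, `frac_T` and
#'   `n_sites_counted`.
#' @export
composition <- function(seqs) {
  ch <- unlist(strsplit(unname(seqs), "", fixed = TRUE))
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"))
  n <- sum(counts)
  if (n == 0L) stop("no unambiguous bases to count")
  list(frac_A = counts[["A"]] / n, frac_C = counts[["C"]] / n,
       frac_G = counts[["G"]] / n, frac_T = counts[["T"]] / n,
       n_sites_counted = n)
}

#' GC fraction of each sequence
#'
#' @param seqs A sequence set.
#' @return Named numeric vector of per-sequence G+C proportions over
#'   unambiguous bases.
#' @export
gc_fraction <- function(seqs) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- sum(ch %in% c("A", "C", "G", "T"))
    if (n == 0L) return(NA_real_)
    sum(ch %in% c("G", "C")) / n
  }, numeric(1))
}

SPECIMEN_COLUMNS <- c("voucher", "species", "genus", "higher_taxon",
                      "location", "sequence_id")

#' Read a specimen table
#'
#' Tab-separated with header columns `voucher`, `species`, `genus`,
#' `higher_taxon`, `location`, `sequence_id`. An empty or `-`
#' `sequence_id` marks a specimen without a usable sequence (failed or
#' ambiguous sequencing) and is stored as `NA`. Taxonomy must be
#' hierarchical: a named species requires a genus, a genus requires a
#' higher taxon.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with one row per specimen.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  validate_specimens(df)
}

#' Validate a specimen data frame
#'
#' @param df Data frame with the specimen-table columns.
#' @return The validated data frame (blank/`-` `sequence_id` as `NA`).
#' @export
validate_specimens <- function(df) {
  missing <- setdiff(SPECIMEN_COLUMNS, names(df))
  if (length(missing) > 0L)
    stop("specimen table lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  df$sequence_id[blank(df$sequence_id) | trimws(df$sequence_id) == "-"] <- NA
  if (anyDuplicated(df$voucher))
    stop("duplicate voucher id(s): ",
         paste(unique(df$voucher[duplicated(df$voucher)]), collapse = ", "))
  bad <- !blank(df$species) & blank(df$genus)
  if (any(bad))
    stop("species without genus for voucher(s): ",
         paste(df$voucher[bad], collapse = ", "))
  bad <- !blank(df$genus) & blank(df$higher_taxon)
  if (any(bad))
    stop("genus without higher taxon for voucher(s): ",
         paste(df$voucher[bad], collapse = ", "))
  df
}

#' Write a specimen table
#'
#' @param df Specimen data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(df, path) {
  out <- df
  out$sequence_id[is.na(out$sequence_id)] <- "-"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove gap characters from aligned sequences
#'
#' @param seqs A sequence set (possibly aligned).
#' @return The same set with all `-` characters removed.
#' @export
degap <- function(seqs) {
  out <- gsub("-", "", seqs, fixed = TRUE)
  attributes(out) <- attributes(seqs)
  names(out) <- names(seqs)
  out
}
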