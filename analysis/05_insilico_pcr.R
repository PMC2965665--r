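#!/usr/bin/env Rscript
# In-silico PCR with the survey primer sets: build a template around
# one clean sequence per species (AT-rich flanks plus the JB3/JB5
# binding sites), amplify virtually, and tally outcome classes.

suppressPackageStartupMessages(library(nemabar))

seqs <- read_fasta("results/dataset/sequences.fasta", aligned = TRUE)
records <- read_specimen_table("results/dataset/specimens.tsv")
truth <- read.delim("results/dataset/truth.tsv")
clean_ids <- truth$sequence_id[!(truth$is_numt | truth$is_contaminant)]
rec1 <- records[records$sequence_id %in% clean_ids, ]
rec1 <- rec1[!duplicated(rec1$species), ]

jb3 <- get_primer("JB3")
jb5 <- get_primer("JB5")
cat(sprintf("primer degeneracies: JB3 %d, JB2 %d, JB5GED %d\n",
            jb3$degeneracy, get_primer("JB2")$degeneracy,
            get_primer("JB5GED")$degeneracy))

set.seed(1)
at_flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE,
                                     prob = c(.27, .12, .19, .42)),
                              collapse = "")
outcomes <- vapply(rec1$sequence_id, function(sid) {
  insert <- gsub("-", "", seqs[[sid]], fixed = TRUE)
  tmpl <- paste0(at_flank(60), jb3$sequence, insert,
                 reverse_complement(jb5$sequence), at_flank(60))
  amplify(tmpl, jb3, jb5,
          expected_len = nchar(jb3$sequence) + nchar(insert) +
            nchar(jb5$sequence))$class
}, character(1))

tt <- tally_success(outcomes)
print(tt)
write.table(tt, "results/pcr_tally.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/pcr_tally.tsv\n")
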