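#!/usr/bin/env Rscript
# Sequence quality control: translation checks under the invertebrate
# mitochondrial code, amino-acid indel detection, composition-outlier
# screen, and NJ-tree long-branch / taxonomic-outlier flags.

suppressPackageStartupMessages(library(nemabar))

seqs <- read_fasta("results/dataset/sequences.fasta", aligned = TRUE)
records <- read_specimen_table("results/dataset/specimens.tsv")

qc <- run_qc(seqs, records)
print(qc)

write.table(qc$report, "results/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(qc$indels))
  write.table(qc$indels, "results/indel_report.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
if (!is.null(qc$tree))
  writeLines(to_newick(qc$tree), "results/qc_tree.nwk")
write_fasta(qc$filtered, "results/filtered.fasta")

truth <- read.delim("results/dataset/truth.tsv")
art <- truth$sequence_id[truth$is_numt | truth$is_contaminant]
caught <- sum(qc$report$verdict[match(art, qc$report$sequence_id)] == "fail")
cat(sprintf("artifact recovery: %d of %d injected artifacts removed\n",
            caught, length(art)))
cat("wrote results/qc_report.tsv, results/filtered.fasta, results/qc_tree.nwk\n")
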