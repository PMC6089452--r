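#!/usr/bin/env Rscript
# Builds the synthetic study cohorts used by the downstream analyses:
# a yeast-like and a human-like iid cohort (no selection; TL length
# medians 49 and 173 nt), and a planted cohort with known uORF/oORF truth.
# Writes FASTA + truth tables under results/.

suppressMessages(library(leaderscan))
dir.create("results", showWarnings = FALSE)

yeast <- generate_cohort(2000, preset = "yeast", mode = "iid", seed = 1001)
human <- generate_cohort(2000, preset = "human", mode = "iid", seed = 1002)
planted <- generate_cohort(1000, preset = "yeast", mode = "planted",
                           prevalence_uORF = 0.3, prevalence_oORF = 0.2,
                           seed = 1003)

write_transcript_fasta(yeast$cohort, "results/sim_yeast_iid.fasta")
write_transcript_fasta(human$cohort, "results/sim_human_iid.fasta")
write_transcript_fasta(planted$cohort, "results/sim_planted.fasta")
write.table(planted$truth$flags, "results/sim_planted_truth_flags.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_orf_table(planted$truth$calls, "results/sim_planted_truth_calls.tsv")

for (nm in c("yeast", "human")) {
  g <- if (nm == "yeast") yeast else human
  lens <- vapply(g$cohort, `[[`, integer(1), "tl_length")
  cat(sprintf("cohort %s-like: n=%d, TL median %d nt (IQR %d-%d)\n",
              nm, length(g$cohort), as.integer(median(lens)),
              as.integer(quantile(lens, .25)),
              as.integer(quantile(lens, .75))))
}
cat(sprintf("planted cohort: %d genes, %d planted uORFs, %d planted oORFs\n",
            nrow(planted$truth$flags), sum(planted$truth$flags$planted_uORF),
            sum(planted$truth$flags$planted_oORF)))
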