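#!/usr/bin/env Rscript
# STN1-like fixtures: wild-type architectures and the re-annotation of the
# engineered point mutants (start knockouts u1/u2, stop knockout s111,
# human double knockout).

suppressMessages(library(leaderscan))
dir.create("results", showWarnings = FALSE)

wt_y <- stn1_fixture("yeastWT")
wt_h <- stn1_fixture("humanWT")
cat("== yeast wild type ==\n"); print(scan_transcript(wt_y$record))
cat("== human wild type ==\n"); print(scan_transcript(wt_h$record))

rows <- list()
for (spec in list(c("yeastWT", "u1"), c("yeastWT", "u2"),
                  c("yeastWT", "s111"),
                  c("humanWT", "human_no_oORF"))) {
  wt <- stn1_fixture(spec[1]); mut <- stn1_fixture(spec[2])
  d <- diff_architecture(scan_transcript(wt$record),
                         scan_transcript(mut$record))
  cat("\n==", spec[1], "->", spec[2],
      " [", paste(mut$substitutions, collapse = " "), "]\n")
  print(d)
  ev <- function(df, verdict) if (nrow(df)) {
    data.frame(mutant = spec[2], event = verdict, start = df$start,
               tags = if ("tags" %in% names(df)) df$tags else verdict)
  }
  rows <- c(rows, list(ev(d$destroyed, "destroyed"), ev(d$created, "created"),
                       ev(d$altered, "altered")))
}
out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
write.table(out, "results/stn1_variant_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_orf_table(scan_transcript(wt_y$record), "results/stn1_yeast_calls.tsv")
write_orf_table(scan_transcript(wt_h$record), "results/stn1_human_calls.tsv")
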