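#!/usr/bin/env Rscript
# Mutant competition read ratios (seed vs PAM-distal mutant) across input
# mixtures, plus the run report figures for the escape experiment.
# Requires 01 and 02 to have run.
suppressPackageStartupMessages(library(crisprEscape))

# competition: 2:1 and 1:2 titer mixes read out by deep sequencing
set.seed(33)
mixes <- c(`2:1` = 2 / 3, `1:2` = 1 / 3)
rows <- do.call(rbind, lapply(names(mixes), function(mx) {
  n <- 10000L
  seed_reads <- rbinom(1, n, mixes[[mx]])
  data.frame(mix = mx, seed_reads = seed_reads,
             distal_reads = n - seed_reads,
             ratio = competition_ratio(seed_reads, n - seed_reads))
}))
print(rows, digits = 3)
write.table(rows, "results/competition_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

files <- render_report("results/escape_run")
message("report figures: ", paste(files, collapse = ", "))
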