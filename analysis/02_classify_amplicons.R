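#!/usr/bin/env Rscript
# Classify the simulated amplicon read pairs: R1/R2 concordance filtering,
# per-read mutation classes, per-position mutated-read proportions,
# positional Z-scores against the non-targeted controls, nucleotide
# diversity and the fraction-mutated time course. Requires
# 01_simulate_escape.R to have run.
suppressPackageStartupMessages(library(crisprEscape))

outdir <- "results/escape_run"
cfg <- read_run_config(file.path(outdir, "config.yaml"))
res <- run_amplicon(cfg)

message("\nPer-sample summary:")
print(res$samples[, c("sample_id", "role", "timepoint", "n_accepted",
                      "fraction_mutated", "diversity")], digits = 3)

message("\nFraction mutated over time (mean of 2 replicates +/- SD):")
print(res$timecourse, digits = 3)

z <- res$zscores
top <- z[order(-z$z), ][1:4, ]
message("\nTop positional enrichment Z-scores (PAM-relative positions):")
print(top, digits = 3)
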