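#!/usr/bin/env Rscript
# Plant large deletions with engineered junction microhomology in a
# synthetic 10 kb amplified region, emit long reads, and call deletions
# back: breakpoints, lengths, homology and genome-translated coordinates.
suppressPackageStartupMessages(library(crisprEscape))

dir.create("results", showWarnings = FALSE)

plants <- data.frame(
  del_start = c(1501L, 4001L, 7001L),
  del_end = c(1800L, 5200L, 7080L),
  mh = c(0L, 6L, 3L)
)
ref <- build_deletion_reference(10000, plants, seed = 71)
lr <- emit_long_reads(ref, cbind(plants[, c("del_start", "del_end")],
                                 frequency = c(0.25, 0.25, 0.2)),
                      n_reads = 400, seq_error_rate = 0.002, seed = 72)

events <- find_deletions(lr$reads, ref)
agg <- aggregate_deletions(events, genome_offset = 19000L)

message("Called deletion classes: ",
        paste(names(table(events$status)), table(events$status),
              sep = "=", collapse = ", "))
message("\nAggregated deletions (genome coordinates = amplicon + 19000):")
print(agg)

write.table(events, "results/longread_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(agg, "results/longread_deletions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_deletion_bed(agg, "results/longread_deletions.bed")
message("\nWrote results/longread_events.tsv, longread_deletions.tsv, ",
        "longread_deletions.bed")
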