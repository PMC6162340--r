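#!/usr/bin/env Rscript
# Analytic expectation: how often should a dark-zone B cell pick up a
# premature stop codon during its divisions?
#
# Walks the per-division risk chain for a 393-nt V gene mutating at
# 1e-3/nt/division, with the deletion rate estimated from published
# load/deletion correlations, and reports the expected stop-codon frequency
# of a two-division snapshot cohort in both rounding modes.

suppressMessages(library(shmstop))
dir.create("results", showWarnings = FALSE)

rep <- run_expectation_workflow(q = 0.064)
print(rep)

rows <- do.call(rbind, lapply(c("printed", "full"), function(mode) {
  ch <- rep[[mode]]
  data.frame(mode = mode, p_m = ch$p_m, p_point = ch$p_point,
             retain_prob = ch$retain_prob, p_del = ch$p_del, p_fs = ch$p_fs,
             p_stop = ch$p_stop,
             expected_frequency = ch$expected_frequency,
             expected_percent = round(100 * ch$expected_frequency, 2))
}))
write.table(rows, "results/expectation_chain.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# sensitivity to the number of dark-zone divisions
sens <- do.call(rbind, lapply(0:6, function(D) {
  ch <- stop_expectation_chain(D = D, rounding = "printed")
  data.frame(D = D, expected_percent = round(100 * ch$expected_frequency, 2))
}))
write.table(sens, "results/expectation_by_divisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nExpected stop frequency by maximum divisions:\n")
print(sens, row.names = FALSE)
cat("\nWith two dark-zone divisions the model expects ~4.1% of DZ cells to",
    "carry a premature stop codon; the burden grows steeply with divisions.\n")
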