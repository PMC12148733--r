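#!/usr/bin/env Rscript
# Compare the two simulated arms with the study's statistics: Mann-Whitney on
# per-patient public-mutation proportions and per-sample MATH, Pearson
# chi-squared on pooled public-driver and neutral-tail contingencies. Also
# reproduces the printed immunohistochemistry contingency statistics that
# anchor the test battery. Requires analysis/01 to have run.

library(tumevo)

files <- list.files("scratch/sim", pattern = "_mutations.tsv$", full.names = TRUE)
if (!length(files)) stop("run analysis/01_simulate_cohorts.R first")

summaries <- lapply(files, function(f) {
  ds <- read_mutation_table(f, sub("_mutations", "_manifest", f))
  summarize_patient(ds, seed = 1)
})
arm <- substr(vapply(summaries, `[[`, character(1), "patient_id"), 1, 2)
cmp <- compare_cohorts(summaries[arm == "CS"], summaries[arm == "SN"],
                       label_a = "continuous_selection",
                       label_b = "selection_then_neutral")
print(cmp)
write.table(comparison_table(cmp), "results/05_cohort_comparison.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# fixed published 2x2 tables (marker high/low counts per cohort)
printed <- data.frame(
  comparison = c("synaptophysin", "chromogranin_a", "SALL4", "MMR_dual_loss"),
  method = c("fisher", "fisher", "fisher", "pearson_chi2"),
  p_value = c(fisher_exact_2x2(rbind(c(2, 50), c(0, 189)))$p_value,
              fisher_exact_2x2(rbind(c(4, 48), c(0, 189)))$p_value,
              fisher_exact_2x2(rbind(c(4, 48), c(1, 188)))$p_value,
              pearson_chi2_2x2(rbind(c(7, 3), c(1, 18)))$p_value))
write.table(printed, "results/05_printed_table_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nPrinted-table statistics:\n")
print(transform(printed, p_value = signif(p_value, 3)), row.names = FALSE)
cat("Tables in results/05_cohort_comparison.tsv and",
    "results/05_printed_table_stats.tsv\n")
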