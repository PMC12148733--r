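# In-code fixtures: small datasets built from count or VAF matrices.

make_counts_dataset <- function(alt, ref, purity = 1, patient = "P1",
                                depth = 200, callable_mb = 35,
                                msi_score = NA_real_) {
  alt <- as.matrix(alt); ref <- as.matrix(ref)
  R <- ncol(alt)
  regs <- colnames(alt)
  if (is.null(regs)) regs <- paste0("R", seq_len(R))
  colnames(alt) <- colnames(ref) <- regs
  n <- nrow(alt)
  muts <- data.frame(chrom = paste0("chr", (seq_len(n) - 1) %% 22 + 1),
                     pos = 100 + seq_len(n), ref_allele = "A", alt_allele = "T",
                     gene = "", is_driver = FALSE, stringsAsFactors = FALSE)
  rownames(alt) <- rownames(ref) <- mutation_ids(muts)
  regions <- data.frame(patient_id = patient,
                        region_id = c(regs, "NORM"),
                        purity = c(rep_len(purity, R), 1),
                        mean_depth = depth,
                        layer = c(rep(c("surface", "deep"), length.out = R), "normal"),
                        msi_score = c(rep(msi_score, R), NA),
                        callable_mb = callable_mb,
                        stringsAsFactors = FALSE)
  multiregion_dataset(patient, regions, muts, alt, ref)
}

# dataset whose observed VAFs equal `v` exactly (alt = v * depth, no sampling)
make_vaf_dataset <- function(v, depth = 100, purity = 1, ...) {
  v <- as.matrix(v)
  alt <- round(v * depth)
  make_counts_dataset(alt, depth - alt, purity = purity, depth = depth, ...)
}

# noise-free dataset from a simulation truth: counts set to their expectations
expected_counts_dataset <- function(sim, depth) {
  truth <- sim$truth
  evaf <- sweep(truth$true_ccf / 2, 2, truth$purity, `*`)
  alt <- round(evaf * round(depth))
  ref <- round(depth) - alt
  ds <- sim$dataset
  multiregion_dataset(ds$patient_id, ds$regions, ds$mutations, alt, ref,
                      drivers = ds$drivers)
}
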