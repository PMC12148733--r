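# tumevo

Multi-region tumor evolution analysis from somatic read-count data.

Multi-region sequencing — several biopsies of one tumor plus a matched
normal — lets you reconstruct how the tumor evolved. `tumevo` implements the
complete analysis chain for per-region alt/ref read counts:

* **CCF estimation and clustering** — VAFs are converted to cancer cell
  fractions via the standard purity/copy-number adjustment
  `CCF = VAF · (ρ·C_T + (1−ρ)·C_N) / (ρ·m)` and clustered with a binomial
  mixture model, `alt_ir ~ Σ_k π_k Binomial(n_ir, ρ_r φ_kr / 2)`, fit by EM
  with BIC model selection (up to 40 clusters, 100 random restarts).
* **Phylogenies** — mutations are classified *public* (present in all
  regions), *private* (exactly one) or *shared* (otherwise) under the
  calling-floor presence rule (alt ≥ 3, VAF ≥ 0.10); rooted neighbor-joining
  trees are built from presence-based Hamming distances so branch lengths are
  in mutation-count units, with trunk length, tree-shape labels
  (`long_trunk_short_branches` vs `short_trunk_long_branches`) and
  trunk/branch driver placement.
* **VAF profiles** — per-sample Gaussian-mixture densities (Mclust method),
  peaks above density 2.0 classified as clonal ([0.40, 1]), subclonal
  ([0.15, 0.40)) or neutral tail ([0, 0.15)); the MATH heterogeneity score
  `100 · 1.4826 · MAD / median`; TMB (high at ≥ 10/Mb) and MSI/dMMR
  (score > 3.5) threshold calls.
* **Cohort statistics** — Fisher exact (probability-mass two-sided rule),
  Pearson chi-squared (uncorrected), Mann–Whitney U (exact/normal switching),
  and a four-contrast cohort comparison report.
* **A clonal-evolution simulator** — generates multi-region read-count
  datasets with full ground truth under two regimes, *continuous selection*
  and *selection then neutral*, differing in late low-CCF passenger load;
  used to validate every downstream stage against planted truth.

See `vignettes/tumor-evolution-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(tumevo)

sim <- simulate_patient("selection_then_neutral", n_regions = 4, seed = 7)
s   <- summarize_patient(sim$dataset, seed = 7)

s$tree
#> <phylo_tree> rooted at normal with 5 leaves; trunk length 80 
#>   public fraction 0.296 -> short_trunk_long_branches 

s$profiles[[1]]
#> <vaf_profile> SIM000007_R1 - 131 VAFs, 2 mixture components
#>   MATH 16.679 | TMB 3.74  
#>   peaks: neutral_tail@0.050(d=4.87), clonal@0.415(d=7.74)
```

The tree's trunk carries the 80 mutations called in all four regions; under
this regime only ~30 % of mutations are public, so the shape is
`short_trunk_long_branches`. The first region's VAF distribution shows a
clonal peak near the expected `purity/2` and a neutral tail below VAF 0.15
from late passenger mutations; MATH ≈ 17 quantifies its spread, and TMB is
131/35 ≈ 3.7 mutations/Mb (not high).

Per-patient tables come from `read_mutation_table()` (a long TSV of
`patient, region, chrom, pos, ref, alt, alt_count, ref_count, gene,
is_driver` rows plus a region manifest; 1-based inclusive coordinates, `"."`
for missing, and unreported (mutation, region) pairs kept distinct from
covered zero-alt sites).

## The analysis workflow

Numbered drivers under `analysis/` run the full study on simulated cohorts
(8 continuous-selection vs 9 selection-then-neutral patients), writing
summary tables under `results/` and bulky per-patient files under `scratch/`:

```sh
Rscript analysis/01_simulate_cohorts.R    # cohorts + ground truth
Rscript analysis/02_ccf_clustering.R      # binomial-mixture CCF clusters
Rscript analysis/03_phylogenies.R         # NJ trees, shapes, driver placement
Rscript analysis/04_vaf_profiles.R        # peaks, MATH, TMB/MSI flags
Rscript analysis/05_cohort_comparison.R   # the four cohort contrasts
```

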