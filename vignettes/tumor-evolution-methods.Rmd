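---
title: "Methods: multi-region tumor evolution analysis with tumevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region tumor evolution analysis with tumevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumevo)
```

## The question the pipeline addresses

Multi-region sequencing of a solid tumor — several spatially separated
biopsies plus a matched normal — exposes its evolutionary history. Mutations
present in every region ("public") were acquired on the trunk of the tumor's
clonal genealogy; mutations confined to one region ("private") or a subset
("shared") mark subclonal diversification. Two qualitative histories leave
distinguishable footprints. Under **continuous selection**, recurrent
selective sweeps keep fixing mutations tumor-wide: public mutations
predominate, phylogenies show a long trunk with short branches, and
per-sample variant-allele-frequency (VAF) distributions concentrate in a
clonal peak. Under **selection followed by neutral growth**, an early sweep
is followed by drift: late passenger mutations accumulate at low cell
fractions, producing a low-VAF "neutral tail", longer branches, and higher
single-sample heterogeneity (MATH) scores.

`tumevo` implements the full analysis chain for read-count data —
CCF conversion and clustering, mutation categorization, neighbor-joining
phylogenies, VAF-distribution profiling, and cohort statistics — together
with a clonal-evolution simulator that generates data under the two regimes
with complete ground truth, so every stage can be validated against planted
truth rather than only against itself.

## Data model and assumptions

A patient is a `multiregion_dataset`: alt/ref read-count matrices over
mutations × tumor regions, plus a region manifest (purity, mean depth,
sampling layer, optional MSI score, callable megabases). Coordinates are
1-based inclusive; a (mutation, region) pair *absent* from the table (`NA`)
is "not called there", which is distinct from a covered site with zero alt
reads. For category classification an uncalled site is treated as absent; for
distance computation its VAF contributes 0. Records with zero total depth are
flagged at construction and excluded from VAF arithmetic.

The core quantitative assumption is the standard diploid heterozygous model:
a mutation at multiplicity 1 on a copy-number-2 segment carried by a fraction
$\phi$ (the cancer cell fraction, CCF) of tumor cells in a sample of purity
$\rho$ has expected VAF $\rho\phi/2$, hence
$\widehat{\phi} = \mathrm{VAF}\cdot\big(\rho\,C_T + (1-\rho)\,C_N\big) / (\rho m)$
in general, capped at 1 by default (a cap of 1.5 is available for LOH-focused
work). Copy-number segments, when supplied, set $C_T$ and the multiplicity
estimate; otherwise all sites are treated as diploid heterozygous.

## The simulator: what it emulates, and what it does not

`simulate_patient()` draws a clone tree (one root clone plus 2–5 subclones by
random recursive attachment), plants trunk mutations on the root and
subclonal mutations across subclones, and samples reads per site as
$\mathrm{alt} \sim \mathrm{Binomial}(\mathrm{round}(d),\ \rho\,\phi/2)$ with
$d = 200$ for tumor regions (normals are recorded at $100\times$), purity
drawn uniformly on $[0.40, 0.95]$ — the floor real studies impose for
evolutionary analysis — and 3–7 regions per tumor at cohort level.

Two design choices deserve justification because the generative model is
genuinely open:

* **Lineage-path compositions.** Each region picks a terminal clone; its
  clone mixture is supported on the root-to-terminal ancestral path, with
  Dirichlet weights and the deepest clone boosted to dominance. Regional
  samples of real tumors are dominated by one lineage with admixed ancestral
  cells, so this is biologically reasonable — and it makes region presence
  patterns laminar (nested or disjoint). Laminar patterns make the
  presence-based Hamming distance exactly tree-additive, which is what lets
  the test suite assert that neighbor joining recovers the planted trunk
  *exactly* on noise-free counts. Subclones sampled by no region have zero
  CCF everywhere and are dropped with their mutations: a sequencing
  experiment can never observe them.
* **Regime parameterization.** The regimes differ only in the late-passenger
  load: `selection_then_neutral` adds the full `n_neutral` budget (default
  150), each passenger private to one region with CCF uniform on (0, 0.2];
  `continuous_selection` applies a weight of 0.1 to that budget. Defaults of
  80 trunk and 40 subclonal mutations give per-region mutation counts of a
  few hundred, typical of exome studies of these tumor types. These values
  are free choices, fixed once and exposed as arguments, not tuned
  quantities.

Deliberately *not* modeled: sequencing error, germline contamination,
indels, copy-number alteration, mutational signatures, and overdispersion
beyond binomial sampling. Passing tests therefore demonstrate correctness of
the inference machinery under the stated model, not robustness to artifacts
of real FFPE exome data — real VAF distributions are noisier, and observed
MATH scores in real cohorts run higher than the binomial-only simulation
produces. All randomness flows from one integer seed; cohort members use
`seed + i`.

## CCF clustering

`fit_binomial_mixture()` is a plain expectation–maximization fit of
$\mathrm{alt}_{ir} \sim \sum_k \pi_k\,\mathrm{Binomial}(n_{ir},\ \rho_r\,\phi_{kr}/2)$,
with the component count chosen by minimum BIC over $K = 1..K_{\max}$
(default 40) and the best of `restarts` (default 100) seed-controlled
initializations per $K$; centers initialize from empirical CCF quantiles with
jitter. Binomial emissions with deterministic EM were chosen over variational
beta-binomial alternatives: the fit is reproducible, its log-likelihood is
provably non-decreasing (asserted per iteration in the tests), and the
emission density matches the read-sampling model of the simulator.
Convergence is a relative log-likelihood change below `tol` (1e-6) within 500
iterations; hitting the cap returns the best-so-far fit flagged
`converged = FALSE`. Mutations uncovered in a region contribute nothing to
the likelihood there — a contract of this implementation, since upstream
callers only report called sites. Empty clusters are dropped after MAP
assignment.

On simulated data with neutral passengers, BIC typically selects more
clusters than the planted clone count: the passengers' CCFs form a continuum
on (0, 0.2] that a finite mixture tiles with several diffuse components. This
is correct behavior of the criterion, not a defect, and is visible in
`results/02_ccf_clusters.tsv`.

## Phylogenies

Presence of a mutation in a region requires `alt_count >= 3` and
`VAF >= 0.10`, echoing the variant-calling floor; both thresholds are
arguments. Categories follow the occupancy rule (all regions → public;
exactly one → private; otherwise → shared). Note the "otherwise" clause puts
a mutation below thresholds everywhere into "shared"; the truth-comparison
helper applies the identical rule to expected VAFs so the two routes remain
comparable.

The default distance is `hamming_presence` — the number of discordantly
called mutations between two regions, with the matched normal as an
all-absent pseudo-leaf — so branch lengths carry mutation-count units. An
`l1_ccf` metric is provided because region trees can equally be built from
CCF profiles. `neighbor_joining()` is the classic Saitou–Nei algorithm with
two pinned conventions: Q-criterion ties break toward the lowest leaf-index
pair, and a negative branch length at a join is clamped to zero with the
deficit transferred to its sibling so the pair's path length is preserved.
The tree is rooted at the normal leaf; the **trunk** is the edge path from
the root to the first branching node, which on noise-free additive data
equals the public-mutation count. Tree shape is `long_trunk_short_branches`
when the public fraction reaches 0.5 (the operationalization of "public
mutations predominate"; the threshold is an argument and is recorded in the
output). Driver mutations are placed on the trunk iff public.

## VAF profiles

Per-region VAF vectors contain the mutations reported with at least one
variant read in that region: a zero-VAF covered site is not a mutation
there, and including the zero spike would manufacture spurious low-VAF
density. The density model is a univariate Gaussian mixture fit by the
Mclust method (unequal variances, BIC over 1–5 components, deterministic
given the seed). Peaks are grid local maxima (step 0.001 on $[0,1]$; the step
is far below the 0.05-wide classification windows, so results are
insensitive to it; grid ties resolve to the lower VAF) whose density exceeds
2.0 — a threshold interpreted on the mixture's probability-density scale,
stated here because density thresholds are meaningless without their scale.
Peak classes use half-open windows fixed as $[0, 0.15)$ neutral tail,
$[0.15, 0.40)$ subclonal, $[0.40, 1]$ clonal: published window definitions
overlap at 0.40, so the convention is pinned and recorded; locations above
0.5 stay clonal rather than being capped, since LOH can push clonal VAFs
past 0.5.

The MATH score is $100 \times 1.4826\,\mathrm{MAD} / \mathrm{median}$ of the
VAFs — the normal-consistent MAD scaling of the original definition — and is
scale-invariant. TMB is mutations per callable megabase with "high" at
$\ge 10$/Mb (boundary inclusive); the MSI/dMMR call is strict:
score $> 3.5$. An absent MSI score yields an absent call, never `FALSE`.

## Cohort statistics

Fisher's exact test uses the probability-mass two-sided rule (sum of tables
at most as probable as observed), the convention that reproduces published
two-sided values from 2×2 marker tables; the doubling rule was rejected after
checking against those values. Pearson's chi-squared is uncorrected by
default — tests labeled "Pearson's" in the literature are — with Yates
available by flag. Mann–Whitney switches from exact enumeration to the
tie-and-continuity-corrected normal approximation above a pooled $n$ of 12 or
in the presence of ties; both routes are checked against a brute-force
enumeration oracle in the tests. No multiple-testing adjustment is applied
inside the comparison report: raw p-values are reported and any FDR layer
belongs to downstream report configuration.

`compare_cohorts()` assembles the four standard contrasts (per-patient
public proportions, pooled public-driver 2×2, pooled neutral-tail 2×2,
per-sample MATH) with medians, means and counts.

## Problem sizes and numerical choices

The analysis drivers simulate 8 continuous-selection and 9
selection-then-neutral patients (the cohort sizes of the motivating study
design) at depth 200; the test suite's regime-contrast battery uses 20
patients per arm, and exactness checks run at depth 2000 or on expected
(noise-free) counts. The cluster search in the driver is capped at $K = 10$
with 10 restarts — the simulated tumors carry at most 6 clones, so the cap
never binds, while the full 40/100 protocol remains the function default.
Binomial probabilities are clamped to $[10^{-9}, 1-10^{-9}]$ inside EM;
cluster CCFs to $[10^{-6}, \mathrm{cap}]$. EM model-selection BIC counts
$(K-1) + K R$ free parameters.

## Known limitations

Region-level trees are not clone trees: no mutation-cluster phylogeny is
reconstructed, and no bootstrap support is computed. The CCF model ignores
subclonal copy number and overdispersion; MATH on deep, clean simulated data
is systematically lower than on real exomes. The simulator's laminar region
compositions cannot produce conflicting shared-mutation patterns, which real
tumors occasionally show (and which make presence distances non-additive);
on such data neighbor joining is a least-squares-like approximation rather
than exact.
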