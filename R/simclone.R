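#' Simulate one patient's multi-region read-count dataset with ground truth
#'
#' Generates a random clone tree (one root clone plus 2-5 subclones attached by
#' random recursive attachment), plants trunk mutations on the root and
#' subclonal mutations across the subclones, mixes clones into regions, and
#' draws per-site read counts. Two evolutionary regimes are contrasted:
#'
#' * `"continuous_selection"` — ongoing subclonal sweeps; late neutral
#'   passengers enter at a configured low weight (`neutral_weight` of
#'   `n_neutral`), so public mutations predominate.
#' * `"selection_then_neutral"` — an early selective phase followed by neutral
#'   growth; the full `n_neutral` late passengers are added, each private to
#'   one region with true CCF drawn uniformly on (0, 0.2], producing a low-VAF
#'   tail and a lower public fraction.
#'
#' Each region's clone composition is supported on a single root-to-clone
#' lineage path: a terminal clone is chosen per region, mixture weights over
#' the clones on its ancestral path are drawn from a symmetric Dirichlet, and
#' the terminal (deepest) clone is boosted to dominance. Lineage-path support
#' makes region presence patterns nested, so presence-based distances between
#' regions are tree-additive and noise-free phylogenies are exactly
#' recoverable.
#'
#' Read counts are drawn per (mutation, region) as
#' `alt ~ Binomial(round(depth), purity * CCF / 2)` for diploid heterozygous
#' multiplicity-1 sites, with `ref = round(depth) - alt`; every mutation is
#' force-called in every tumor region (covered with zero alt reads where the
#' lineage is absent).
#'
#' @param regime `"continuous_selection"` or `"selection_then_neutral"`.
#' @param n_regions Number of tumor regions, 2-7.
#' @param depth Mean tumor sequencing depth (default 200, as in deep
#'   multi-region WES; the matched normal is recorded at half this, 100).
#' @param purity Tumor purity, recycled across regions; `NULL` (default) draws
#'   each region's purity uniformly on \[0.40, 0.95\].
#' @param n_trunk Trunk (root-clone) mutation count.
#' @param n_subclonal Mutations distributed across subclones.
#' @param n_neutral Late neutral passenger budget (fully used in
#'   `selection_then_neutral`; scaled by `neutral_weight` in
#'   `continuous_selection`).
#' @param neutral_weight Fraction of `n_neutral` applied in the
#'   continuous-selection regime (default 0.1).
#' @param n_subclones Number of subclones; `NULL` draws uniformly from 2-5.
#' @param callable_mb Callable megabases recorded in the manifest (default 35).
#' @param seed Integer seed; identical seeds and parameters give identical
#'   output.
#'
#' @return A list with elements `dataset` (a [multiregion_dataset()]) and
#'   `truth` (class `simulation_truth`: `clone_tree` data frame
#'   (`clone_id, parent_id, n_new_mutations`), `mutation` data frame
#'   (`mut_id, clone_id, true_category, is_neutral`), `true_ccf` matrix
#'   (mutations x regions), `regime`, and the drawn `purity`).
#' @export
simulate_patient <- function(regime = c("continuous_selection", "selection_then_neutral"),
                             n_regions = 5, depth = 200, purity = NULL,
                             n_trunk = 80, n_subclonal = 40, n_neutral = 150,
                             neutral_weight = 0.1, n_subclones = NULL,
                             callable_mb = 35, seed = 1,
                             patient_id = sprintf("SIM%06d", seed %% 1000000L)) {
  regime <- match.arg(regime)
  stopifnot(n_regions >= 2, n_regions <= 7, depth > 0)
  set.seed(seed)

  n_sub <- if (is.null(n_subclones)) sample(2:5, 1) else as.integer(n_subclones)
  if (n_sub < 0) stop("n_subclones must be non-negative")
  if (n_sub == 0 && n_subclonal > 0) {
    stop("configuration error: subclonal mutations requested without subclones")
  }
  if (n_sub > 0 && n_subclonal < n_sub) {
    stop("configuration error: ", n_sub, " subclones exceed the subclonal mutation budget (",
         n_subclonal, ")")
  }
  # clone 1 is the root; subclones attach to a uniformly chosen earlier clone
  parent <- c(NA_integer_, vapply(seq_len(n_sub) + 1L, function(k) {
    sample.int(k - 1L, 1)
  }, integer(1)))
  n_clones <- n_sub + 1L

  # mutations per clone: trunk on root, the rest spread evenly (each subclone >= 1)
  per_sub <- if (n_sub > 0) {
    ps <- rep(n_subclonal %/% n_sub, n_sub)
    extra <- n_subclonal %% n_sub
    if (extra > 0) ps[seq_len(extra)] <- ps[seq_len(extra)] + 1L
    ps
  } else integer(0)
  n_new <- c(n_trunk, per_sub)

  anc <- .ancestor_paths(parent)          # list: clone -> root..clone path
  if (!is.null(purity)) {
    pur <- rep_len(purity, n_regions)
    if (any(pur <= 0 | pur > 1)) stop("purity must lie in (0, 1]")
  } else {
    pur <- stats::runif(n_regions, 0.40, 0.95)
  }

  # region terminal clones: cover as many subclones as possible, then random
  if (n_sub > 0) {
    subclones <- seq_len(n_sub) + 1L
    covered <- subclones[sample.int(n_sub, min(n_sub, n_regions))]
    extra_r <- n_regions - length(covered)
    terminal <- c(covered,
                  if (extra_r > 0) subclones[sample.int(n_sub, extra_r, replace = TRUE)])
    terminal <- terminal[sample.int(length(terminal))]  # shuffle region order
  } else {
    terminal <- rep(1L, n_regions)        # single-clone limit: root only
  }

  # compositions: Dirichlet over the lineage path, deepest clone boosted
  frac <- matrix(0, n_clones, n_regions)  # clone x region fractions
  for (r in seq_len(n_regions)) {
    path <- anc[[terminal[r]]]
    w <- stats::rgamma(length(path), shape = 1.5)
    w[length(path)] <- w[length(path)] + 1.5 * sum(w)  # dominant terminal clone
    frac[path, r] <- w / sum(w)
  }

  # clone-borne mutations and their regional CCFs
  clone_of <- rep(seq_len(n_clones), n_new)
  subtree <- .subtree_members(parent)     # clone -> clones at/below it
  ccf_clone <- matrix(0, n_clones, n_regions)
  for (cl in seq_len(n_clones)) {
    ccf_clone[cl, ] <- colSums(frac[subtree[[cl]], , drop = FALSE])
  }
  # drop subclones that no region samples (zero CCF everywhere: unobservable)
  observable <- rowSums(ccf_clone) > 1e-12
  keep <- observable[clone_of]
  clone_of <- clone_of[keep]

  n_neut <- if (regime == "selection_then_neutral") n_neutral else round(neutral_weight * n_neutral)
  neut_region <- if (n_neut > 0) sample.int(n_regions, n_neut, replace = TRUE) else integer(0)
  neut_ccf <- if (n_neut > 0) stats::runif(n_neut, 0, 0.2) else numeric(0)

  n_mut <- length(clone_of) + n_neut
  region_ids <- sprintf("%s_R%d", patient_id, seq_len(n_regions))
  true_ccf <- matrix(0, n_mut, n_regions)
  true_ccf[seq_along(clone_of), ] <- ccf_clone[clone_of, , drop = FALSE]
  if (n_neut > 0) {
    true_ccf[cbind(length(clone_of) + seq_len(n_neut), neut_region)] <- neut_ccf
  }

  occ <- true_ccf > 1e-12
  n_occ <- rowSums(occ)
  category <- ifelse(n_occ == n_regions, "public",
                     ifelse(n_occ == 1L, "private", "shared"))

  # synthetic coordinates: chromosome 1..22 round-robin, unique positions
  chrom <- paste0("chr", (seq_len(n_mut) - 1L) %% 22L + 1L)
  pos <- 1000L + 37L * seq_len(n_mut)
  bases <- c("A", "C", "G", "T")
  ref_allele <- bases[(seq_len(n_mut) - 1L) %% 4L + 1L]
  alt_allele <- bases[seq_len(n_mut) %% 4L + 1L]

  # a few trunk mutations carry driver-gene labels
  gene <- rep("", n_mut)
  is_driver <- rep(FALSE, n_mut)
  driver_pool <- c("TP53", "APC", "KRAS", "ARID2", "SMAD4", "PIK3CA")
  n_drv <- min(length(driver_pool), max(2L, round(0.05 * n_mut)))
  drv_idx <- sample.int(n_mut, n_drv)
  gene[drv_idx] <- driver_pool[seq_len(n_drv)]
  is_driver[drv_idx] <- TRUE

  nread <- as.integer(round(depth))
  alt <- matrix(NA_integer_, n_mut, n_regions)
  for (r in seq_len(n_regions)) {
    p <- pmin(1, pur[r] * true_ccf[, r] / 2)
    alt[, r] <- stats::rbinom(n_mut, nread, p)
  }
  ref <- nread - alt
  mut_ids <- paste(chrom, pos, ref_allele, alt_allele, sep = ":")
  dimnames(alt) <- dimnames(ref) <- dimnames(true_ccf) <- list(mut_ids, region_ids)

  regions <- data.frame(
    patient_id = patient_id,
    region_id = c(region_ids, paste0(patient_id, "_N")),
    purity = c(pur, 1),
    mean_depth = c(rep(depth, n_regions), depth / 2),
    layer = c(rep(c("surface", "deep"), length.out = n_regions), "normal"),
    msi_score = c(round(stats::runif(n_regions, 0, 1), 3), NA_real_),
    callable_mb = callable_mb,
    stringsAsFactors = FALSE)

  mutations <- data.frame(chrom = chrom, pos = pos, ref_allele = ref_allele,
                          alt_allele = alt_allele, gene = gene,
                          is_driver = is_driver, stringsAsFactors = FALSE)
  ds <- multiregion_dataset(patient_id, regions, mutations, alt, ref,
                            drivers = unique(gene[is_driver]))

  truth <- structure(
    list(clone_tree = data.frame(clone_id = seq_len(n_clones),
                                 parent_id = parent,
                                 n_new_mutations = n_new),
         mutation = data.frame(mut_id = mut_ids,
                               clone_id = c(clone_of, rep(NA_integer_, n_neut)),
                               true_category = category,
                               is_neutral = c(rep(FALSE, length(clone_of)),
                                              rep(TRUE, n_neut)),
                               stringsAsFactors = FALSE),
         true_ccf = true_ccf,
         clone_fractions = frac,
         regime = regime,
         purity = stats::setNames(pur, region_ids)),
    class = "simulation_truth")
  list(dataset = ds, truth = truth)
}

.ancestor_paths <- function(parent) {
  lapply(seq_along(parent), function(cl) {
    path <- cl
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  })
}

.subtree_members <- function(parent) {
  anc <- .ancestor_paths(parent)
  lapply(seq_along(parent), function(cl) {
    which(vapply(anc, function(p) cl %in% p, logical(1)))
  })
}

#' Simulate a cohort of patients under one evolutionary regime
#'
#' Per-patient seeds are `seed + i` (deterministic in the master seed); region
#' counts are drawn uniformly from 3-7 per patient, mirroring multi-region
#' sampling of 3-7 locations per tumor.
#'
#' @param regime Passed to [simulate_patient()].
#' @param n_patients Number of patients (>= 1).
#' @param seed Master integer seed.
#' @param overrides Named list of [simulate_patient()] arguments applied to
#'   every patient (e.g. `list(n_neutral = 300)`).
#' @return List of per-patient lists `(dataset, truth)`.
#' @export
simulate_cohort <- function(regime, n_patients, seed = 1, overrides = list()) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  n_regions <- sample(3:7, n_patients, replace = TRUE)
  prefix <- if (startsWith(regime, "cont")) "CS" else "SN"
  lapply(seq_len(n_patients), function(i) {
    args <- list(regime = regime, n_regions = n_regions[i], seed = seed + i,
                 patient_id = sprintf("%s%03d", prefix, i))
    args[names(overrides)] <- overrides
    do.call(simulate_patient, args)
  })
}

#' Threshold-consistent expected mutation categories from simulation truth
#'
#' Applies the same presence rule as [classify_mutations()] to the *expected*
#' data: a mutation counts as present in a region when its expected VAF
#' (`purity * CCF / 2`) reaches `min_vaf` and its expected alt-read count
#' (`depth * expected VAF`) reaches `min_alt`. This is the noise-free category
#' the classifier should recover at large depth.
#'
#' @param truth A `simulation_truth`.
#' @param depth Sequencing depth used in the simulation.
#' @param min_vaf,min_alt Presence thresholds (defaults 0.10 and 3).
#' @return Named character vector of categories (`public`/`shared`/`private`).
#' @export
truth_categories <- function(truth, depth, min_vaf = 0.10, min_alt = 3) {
  evaf <- sweep(truth$true_ccf / 2, 2, truth$purity, `*`)
  present <- evaf >= min_vaf & evaf * round(depth) >= min_alt
  n <- rowSums(present)
  out <- ifelse(n == ncol(present), "public", ifelse(n == 1L, "private", "shared"))
  stats::setNames(out, rownames(truth$true_ccf))
}

#' Write a simulation truth table to TSV
#'
#' Emits one row per mutation with its true category and per-region true CCF.
#'
#' @param truth A `simulation_truth`.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_truth_table <- function(truth, path) {
  out <- cbind(truth$mutation,
               as.data.frame(truth$true_ccf, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(out)
}
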