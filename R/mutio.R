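#' Construct a multi-region mutation dataset
#'
#' The central container of the package: one patient's somatic mutations
#' observed across several tumor regions (plus one matched normal), stored as
#' aligned alt/ref read-count matrices. An `NA` entry means the mutation was
#' not reported for that region ("absent", zero evidence); a numeric entry with
#' `alt = 0` means the site was covered there but no variant reads were seen.
#' The two are deliberately distinct and survive a write/read round trip.
#'
#' @param patient_id Patient identifier.
#' @param regions Data frame with columns `patient_id`, `region_id`, `purity`,
#'   `mean_depth`, `layer` (one of `"surface"`, `"deep"`, `"normal"`),
#'   `msi_score` (may be `NA`) and `callable_mb`. Exactly one region must have
#'   `layer == "normal"`.
#' @param mutations Data frame with one row per mutation: columns `chrom`,
#'   `pos` (1-based), `ref_allele`, `alt_allele`, `gene` (may be `""`),
#'   `is_driver` (logical). Row identity is `chrom:pos:ref:alt`, unique within
#'   the patient.
#' @param alt,ref Integer matrices, mutations x tumor regions, with
#'   `rownames` equal to the mutation identifiers and `colnames` equal to the
#'   tumor region ids. `NA` marks a mutation not reported in a region.
#' @param drivers Character vector of driver gene symbols.
#'
#' @return An object of class `multiregion_dataset`.
#' @export
multiregion_dataset <- function(patient_id, regions, mutations, alt, ref,
                                drivers = character()) {
  regions <- as.data.frame(regions)
  mutations <- as.data.frame(mutations)
  .validate_regions(regions, patient_id)
  tumor_ids <- regions$region_id[regions$layer != "normal"]

  mut_ids <- mutation_ids(mutations)
  if (anyDuplicated(mut_ids)) {
    stop("duplicate mutation identities within patient '", patient_id, "': ",
         paste(unique(mut_ids[duplicated(mut_ids)]), collapse = ", "))
  }
  alt <- as.matrix(alt)
  ref <- as.matrix(ref)
  storage.mode(alt) <- "integer"
  storage.mode(ref) <- "integer"
  if (!identical(dim(alt), dim(ref))) {
    stop("alt and ref matrices must have identical dimensions")
  }
  if (is.null(rownames(alt))) rownames(alt) <- mut_ids
  if (is.null(rownames(ref))) rownames(ref) <- mut_ids
  if (!setequal(colnames(alt), tumor_ids)) {
    stop("count matrix regions do not match the manifest's tumor regions for patient '",
         patient_id, "'")
  }
  alt <- alt[mut_ids, tumor_ids, drop = FALSE]
  ref <- ref[mut_ids, tumor_ids, drop = FALSE]
  if (any(!is.na(alt) & alt < 0) || any(!is.na(ref) & ref < 0)) {
    stop("read counts must be non-negative")
  }
  if (any(is.na(alt) != is.na(ref))) {
    stop("alt/ref missingness must agree: a (mutation, region) pair is either reported with both counts or absent")
  }
  zero_depth <- !is.na(alt) & (alt + ref) == 0L
  if (any(zero_depth)) {
    warning(sum(zero_depth), " covered (mutation, region) entries have zero total depth; ",
            "they are flagged and excluded from VAF-based computations")
  }
  structure(
    list(patient_id = patient_id,
         regions = regions,
         mutations = mutations,
         alt = alt, ref = ref,
         zero_depth = zero_depth,
         drivers = unique(as.character(drivers))),
    class = "multiregion_dataset")
}

.validate_regions <- function(regions, patient_id) {
  needed <- c("patient_id", "region_id", "purity", "mean_depth", "layer", "callable_mb")
  missing_cols <- setdiff(needed, names(regions))
  if (length(missing_cols)) {
    stop("region manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(regions$patient_id == patient_id)) {
    stop("manifest/table patient mismatch: manifest lists patients ",
         paste(unique(regions$patient_id), collapse = ", "),
         " but the dataset is for '", patient_id, "'")
  }
  if (!all(regions$layer %in% c("surface", "deep", "normal"))) {
    stop("region layer must be one of surface, deep, normal")
  }
  if (sum(regions$layer == "normal") != 1L) {
    stop("exactly one region per patient must have layer = normal")
  }
  tum <- regions[regions$layer != "normal", ]
  bad <- !is.na(tum$purity) & (tum$purity <= 0 | tum$purity > 1)
  if (any(bad)) stop("tumor region purity must lie in (0, 1]")
  if (any(regions$mean_depth <= 0)) stop("mean_depth must be positive")
  if (any(regions$callable_mb <= 0)) stop("callable_mb must be positive")
  invisible(regions)
}

#' Mutation identifiers (chrom:pos:ref:alt)
#'
#' @param x A `multiregion_dataset` or a mutation data frame.
#' @return Character vector of identifiers.
#' @export
mutation_ids <- function(x) {
  if (inherits(x, "multiregion_dataset")) x <- x$mutations
  paste(x$chrom, x$pos, x$ref_allele, x$alt_allele, sep = ":")
}

#' Tumor region identifiers of a dataset
#' @param ds A `multiregion_dataset`.
#' @return Character vector of tumor region ids (manifest order).
#' @export
tumor_regions <- function(ds) {
  ds$regions$region_id[ds$regions$layer != "normal"]
}

#' Tumor purities aligned to [tumor_regions()]
#' @param ds A `multiregion_dataset`.
#' @return Named numeric vector of purities.
#' @export
tumor_purity <- function(ds) {
  tum <- ds$regions[ds$regions$layer != "normal", ]
  stats::setNames(tum$purity, tum$region_id)[tumor_regions(ds)]
}

#' Number of mutations in a dataset
#' @param ds A `multiregion_dataset`.
#' @return Integer count.
#' @export
n_mutations <- function(ds) nrow(ds$alt)

#' @export
print.multiregion_dataset <- function(x, ...) {
  cat("<multiregion_dataset> patient", x$patient_id, "\n")
  cat("  ", n_mutations(x), "mutations x", length(tumor_regions(x)),
      "tumor regions (+1 normal)\n")
  cat("  drivers:", if (length(x$drivers)) paste(x$drivers, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' VAF matrix of a dataset
#'
#' Variant allele frequency alt/(alt+ref) per (mutation, region). Absent
#' entries are `NA`; covered entries with zero total depth are also `NA`
#' (flagged at construction, never silently divided).
#'
#' @param ds A `multiregion_dataset`.
#' @return Numeric matrix, mutations x tumor regions.
#' @export
vaf_matrix <- function(ds) {
  tot <- ds$alt + ds$ref
  v <- ds$alt / tot
  v[ds$zero_depth] <- NA_real_
  v
}

# ---- tabular IO ------------------------------------------------------------

MUTATION_COLS <- c("patient", "region", "chrom", "pos", "ref", "alt",
                   "alt_count", "ref_count", "gene", "is_driver")
MANIFEST_COLS <- c("patient_id", "region_id", "purity", "mean_depth", "layer",
                   "msi_score", "callable_mb")

.read_tsv <- function(path, as_character = FALSE) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = ".", check.names = FALSE,
                    colClasses = if (as_character) "character" else NA)
}

#' Read a mutation table and region manifest into a dataset
#'
#' The mutation table is a long TSV (one row per reported (mutation, region)
#' pair) with header columns `patient, region, chrom, pos, ref, alt,
#' alt_count, ref_count, gene, is_driver`; the manifest is a TSV with the
#' [multiregion_dataset()] region columns. Coordinates are 1-based inclusive
#' (MAF convention). Missing values are written as `"."`. A (mutation, region)
#' pair not listed in the table is recorded as absent (`NA` counts), which is
#' distinct from a listed pair with `alt_count = 0`.
#'
#' @param path Path to the mutation TSV.
#' @param manifest Path to the region manifest TSV.
#' @return A `multiregion_dataset`.
#' @export
read_mutation_table <- function(path, manifest) {
  # allele columns must stay character ("T" would otherwise parse as logical)
  tab <- .read_tsv(path, as_character = TRUE)
  man <- .read_tsv(manifest)
  missing_cols <- setdiff(MUTATION_COLS, names(tab))
  if (length(missing_cols)) {
    stop("mutation table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(tab$pos))
  altc <- suppressWarnings(as.integer(tab$alt_count))
  refc <- suppressWarnings(as.integer(tab$ref_count))
  bad <- which(is.na(pos) | is.na(altc) | is.na(refc) | altc < 0 | refc < 0)
  if (length(bad)) {
    stop("malformed mutation row at line ", bad[1] + 1L,  # +1 for the header
         " of ", path, ": pos/alt_count/ref_count must be non-negative integers")
  }
  tab$pos <- pos; tab$alt_count <- altc; tab$ref_count <- refc

  patient <- unique(c(tab$patient, man$patient_id))
  if (length(patient) != 1L) {
    stop("manifest/table patient mismatch: found ", paste(patient, collapse = ", "))
  }
  unknown <- setdiff(unique(tab$region), man$region_id)
  if (length(unknown)) {
    stop("mutation table refers to regions absent from the manifest: ",
         paste(unknown, collapse = ", "))
  }
  normal_id <- man$region_id[man$layer == "normal"]
  if (any(tab$region %in% normal_id)) {
    stop("somatic mutation rows may not be assigned to the normal region")
  }

  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  if (anyDuplicated(paste(key, tab$region))) {
    dup <- which(duplicated(paste(key, tab$region)))[1]
    stop("duplicate mutation row at line ", dup + 1L, " of ", path,
         ": (", key[dup], ", ", tab$region[dup], ") listed twice")
  }

  mut_ids <- unique(key)
  first <- tab[!duplicated(key), , drop = FALSE]
  mutations <- data.frame(
    chrom = first$chrom, pos = first$pos,
    ref_allele = first$ref, alt_allele = first$alt,
    gene = ifelse(is.na(first$gene), "", first$gene),
    is_driver = .as_flag(first$is_driver),
    stringsAsFactors = FALSE)
  # consistency: gene/is_driver must not contradict across regions
  for (cl in c("gene", "is_driver")) {
    byk <- tapply(tab[[cl]], key, function(z) length(unique(z[!is.na(z)])))
    if (any(byk > 1)) {
      stop("inconsistent '", cl, "' annotation across regions for mutation ",
           names(byk)[which(byk > 1)[1]])
    }
  }

  tumor_ids <- man$region_id[man$layer != "normal"]
  alt <- matrix(NA_integer_, length(mut_ids), length(tumor_ids),
                dimnames = list(mut_ids, tumor_ids))
  ref <- alt
  alt[cbind(match(key, mut_ids), match(tab$region, tumor_ids))] <- tab$alt_count
  ref[cbind(match(key, mut_ids), match(tab$region, tumor_ids))] <- tab$ref_count

  drivers <- unique(mutations$gene[mutations$is_driver & nzchar(mutations$gene)])
  multiregion_dataset(patient, man, mutations, alt, ref, drivers)
}

.as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write a dataset back to the mutation-table / manifest TSV pair
#'
#' Inverse of [read_mutation_table()]: only reported (non-absent) entries are
#' emitted, so the absent-vs-zero-alt distinction round-trips. Files are UTF-8,
#' tab-separated, with `"."` for missing values.
#'
#' @param ds A `multiregion_dataset`.
#' @param path Output path for the mutation TSV.
#' @param manifest Output path for the manifest TSV.
#' @return Invisibly, `ds`.
#' @export
write_mutation_table <- function(ds, path, manifest) {
  ids <- mutation_ids(ds)
  regs <- tumor_regions(ds)
  idx <- which(!is.na(ds$alt), arr.ind = TRUE)
  m <- ds$mutations[idx[, 1], , drop = FALSE]
  out <- data.frame(
    patient = ds$patient_id,
    region = regs[idx[, 2]],
    chrom = m$chrom, pos = m$pos, ref = m$ref_allele, alt = m$alt_allele,
    alt_count = ds$alt[idx], ref_count = ds$ref[idx],
    gene = ifelse(nzchar(m$gene), m$gene, NA_character_),
    is_driver = m$is_driver,
    stringsAsFactors = FALSE)
  out <- out[order(match(out$region, regs), idx[, 1]), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  utils::write.table(ds$regions[, intersect(MANIFEST_COLS, names(ds$regions))],
                     manifest, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(ds)
}

#' Read copy-number segments (BED-like TSV, 1-based inclusive)
#'
#' Columns `chrom, start, end, total_cn, minor_cn`. Coordinates are 1-based
#' inclusive on both ends — a deliberate divergence from BED half-open, chosen
#' to match the MAF convention used by the mutation table.
#'
#' @param path Path to the TSV.
#' @return Data frame of validated segments.
#' @export
read_cn_segments <- function(path) {
  seg <- .read_tsv(path)
  needed <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (length(setdiff(needed, names(seg)))) {
    stop("copy-number table must have columns ", paste(needed, collapse = ", "))
  }
  if (any(seg$start > seg$end)) stop("segment start must be <= end")
  if (any(seg$minor_cn > seg$total_cn)) stop("minor_cn must be <= total_cn")
  if (any(seg$total_cn < 0)) stop("copy numbers must be non-negative")
  seg
}

#' Select driver-gene candidates supported by two independent methods
#'
#' Intersects two per-gene p-value maps (e.g. from two driver-discovery
#' methods run externally) and keeps genes significant in both, with strict
#' inequality at `alpha`.
#'
#' @param pvals_a,pvals_b Named numeric vectors of per-gene p-values in
#'   `[0, 1]`.
#' @param alpha Significance cutoff (default 0.05); a gene with p exactly
#'   equal to `alpha` in either list is excluded.
#' @return Character vector of gene names significant in both lists.
#' @export
select_drivers <- function(pvals_a, pvals_b, alpha = 0.05) {
  for (p in list(pvals_a, pvals_b)) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      stop("p-value vectors must be named by gene")
    }
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
      stop("p-values must lie in [0, 1]")
    }
  }
  sort(intersect(names(pvals_a)[pvals_a < alpha], names(pvals_b)[pvals_b < alpha]))
}
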