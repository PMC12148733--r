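#' VAFs observed in one region
#'
#' The per-region VAF vector over mutations reported there with at least one
#' variant read (a covered site with zero alt reads is not a mutation in that
#' region and is excluded, as are zero-depth entries).
#'
#' @param ds A `multiregion_dataset`.
#' @param region_id A tumor region id.
#' @return Numeric vector of VAFs.
#' @export
region_vafs <- function(ds, region_id) {
  if (!region_id %in% tumor_regions(ds)) {
    stop("unknown tumor region '", region_id, "'")
  }
  v <- vaf_matrix(ds)[, region_id]
  a <- ds$alt[, region_id]
  unname(v[!is.na(v) & !is.na(a) & a >= 1])
}

#' Fit a univariate Gaussian mixture to a VAF sample
#'
#' EM fit via the Mclust method with unequal variances (model "V", falling
#' back to equal variances if needed), component count chosen by BIC over
#' `1..max_components`. The fit is deterministic given the seed.
#'
#' @param vafs Numeric vector of VAFs, length >= 10.
#' @param max_components Largest component count considered (default 5).
#' @param seed Integer seed.
#' @return Object of class `vaf_mixture`: `components` data frame
#'   (`weight, mean, sd`), `G`, `log_likelihood`, `bic`.
#' @export
fit_vaf_density <- function(vafs, max_components = 5, seed = 1) {
  if (length(vafs) < 10) {
    stop("insufficient data: at least 10 VAF values are required (got ",
         length(vafs), ")")
  }
  if (any(vafs < 0 | vafs > 1)) stop("VAFs must lie in [0, 1]")
  set.seed(seed)
  fit <- Mclust(vafs, G = seq_len(max_components),
                modelNames = c("V", "E"), verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  p <- fit$parameters
  sds <- sqrt(p$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, fit$G)
  structure(
    list(components = data.frame(weight = p$pro, mean = p$mean, sd = sds,
                                 row.names = NULL),
         G = fit$G,
         log_likelihood = fit$loglik,
         bic = fit$bic),
    class = "vaf_mixture")
}

#' Mixture probability density
#' @param components Data frame `weight, mean, sd` (or a `vaf_mixture`).
#' @param x Points at which to evaluate.
#' @return Density values.
#' @export
mixture_density <- function(components, x) {
  if (inherits(components, "vaf_mixture")) components <- components$components
  if (!nrow(components)) return(rep(0, length(x)))
  rowSums(vapply(seq_len(nrow(components)), function(k) {
    components$weight[k] * stats::dnorm(x, components$mean[k], components$sd[k])
  }, numeric(length(x))))
}

#' Locate density peaks of a VAF mixture
#'
#' Local maxima of the mixture density on a grid of step `grid_step` over
#' `[0, 1]` whose density exceeds `density_min` (default 2.0, on the
#' probability-density scale of the univariate mixture). Grid plateaus are
#' resolved to the lower VAF; the grid endpoints can carry peaks.
#'
#' @param components Data frame `weight, mean, sd` or a `vaf_mixture`.
#' @param density_min Minimum density for a reported peak (default 2).
#' @param grid_step Grid resolution (default 0.001).
#' @return Data frame `location, density` (possibly zero rows).
#' @export
find_peaks <- function(components, density_min = 2.0, grid_step = 0.001) {
  if (inherits(components, "vaf_mixture")) components <- components$components
  if (is.null(components) || !nrow(components)) {
    return(data.frame(location = numeric(0), density = numeric(0)))
  }
  x <- seq(0, 1, by = grid_step)
  d <- mixture_density(components, x)
  n <- length(x)
  left <- c(-Inf, d[-n])   # sentinels let the endpoints carry peaks
  right <- c(d[-1], -Inf)
  # strict rise from the left so a flat-topped maximum reports its lower end;
  # interior plateau points (d == left) are excluded
  is_peak <- d > left & d >= right
  keep <- is_peak & d > density_min
  res <- data.frame(location = x[keep], density = d[keep])
  res[order(res$location), , drop = FALSE]
}

#' Classify peak locations with the clonal / subclonal / neutral-tail windows
#'
#' Half-open windows fixed as `[0, 0.15)` neutral tail, `[0.15, 0.40)`
#' subclonal, `[0.40, 1]` clonal. Locations above 0.5 (possible under LOH)
#' remain clonal.
#'
#' @param peaks Numeric vector of peak locations in `[0, 1]`, or the data
#'   frame returned by [find_peaks()].
#' @return Character vector (or the input data frame with a `class` column).
#' @export
classify_peaks <- function(peaks) {
  df <- NULL
  if (is.data.frame(peaks)) {
    df <- peaks
    peaks <- peaks$location
  }
  if (any(peaks < 0 | peaks > 1)) stop("peak locations must lie in [0, 1]")
  cls <- ifelse(peaks < 0.15, "neutral_tail",
                ifelse(peaks < 0.40, "subclonal", "clonal"))
  if (!is.null(df)) {
    df$class <- cls
    return(df)
  }
  cls
}

#' MATH score of a VAF sample
#'
#' Mutant-allele tumor heterogeneity: the ratio of the width to the center of
#' the VAF distribution, `100 * 1.4826 * MAD / median` with the
#' normal-consistent MAD scaling.
#'
#' @param vafs Numeric vector, length >= 2, median > 0.
#' @return Non-negative number; 0 for a constant vector, and invariant under
#'   positive rescaling of `vafs`.
#' @export
math_score <- function(vafs) {
  if (length(vafs) < 2) stop("MATH requires at least 2 VAF values")
  med <- stats::median(vafs)
  if (med <= 0) stop("undefined MATH score: median VAF is not positive")
  100 * stats::mad(vafs, constant = 1.4826) / med
}

#' Tumor mutation burden and threshold flags
#'
#' `tmb = n_mutations / callable_mb`; high TMB at `tmb >= 10` mutations/Mb
#' (boundary inclusive); MSI/dMMR call at `msi_score > 3.5` (strict), absent
#' when no MSI score is supplied.
#'
#' @param n_mutations Non-negative mutation count.
#' @param callable_mb Callable megabases, > 0.
#' @param msi_score MSI score (>= 0) or `NA`/`NULL` when unavailable.
#' @return List with `tmb`, `high_tmb`, `dmmr_call` (`NA` if no MSI score).
#' @export
tmb_and_flags <- function(n_mutations, callable_mb, msi_score = NULL) {
  if (is.null(msi_score)) msi_score <- NA_real_
  if (n_mutations < 0 || callable_mb <= 0 || (!is.na(msi_score) && msi_score < 0)) {
    stop("n_mutations and msi_score must be non-negative and callable_mb positive")
  }
  tmb <- n_mutations / callable_mb
  list(tmb = tmb,
       high_tmb = tmb >= 10,
       dmmr_call = if (is.na(msi_score)) NA else msi_score > 3.5)
}

#' Full VAF profile of one region
#'
#' Combines [region_vafs()], [fit_vaf_density()], [find_peaks()],
#' [classify_peaks()], [math_score()] and [tmb_and_flags()] for one tumor
#' region.
#'
#' @inheritParams region_vafs
#' @inheritParams fit_vaf_density
#' @param density_min Peak density threshold (default 2).
#' @return Object of class `vaf_profile`: `region_id`, `vafs`, `components`,
#'   `peaks` (with `class` column), `has_neutral_tail`, `math_score`, `tmb`,
#'   `high_tmb`, `dmmr_call`.
#' @export
vaf_profile <- function(ds, region_id, max_components = 5, density_min = 2.0,
                        seed = 1) {
  vafs <- region_vafs(ds, region_id)
  mix <- fit_vaf_density(vafs, max_components = max_components, seed = seed)
  peaks <- classify_peaks(find_peaks(mix, density_min = density_min))
  reg <- ds$regions[ds$regions$region_id == region_id, ]
  flags <- tmb_and_flags(length(vafs), reg$callable_mb,
                         if ("msi_score" %in% names(reg)) reg$msi_score else NULL)
  structure(
    list(region_id = region_id,
         vafs = vafs,
         components = mix$components,
         G = mix$G,
         peaks = peaks,
         has_neutral_tail = any(peaks$class == "neutral_tail"),
         math_score = math_score(vafs),
         tmb = flags$tmb, high_tmb = flags$high_tmb, dmmr_call = flags$dmmr_call),
    class = "vaf_profile")
}

#' @export
print.vaf_profile <- function(x, ...) {
  cat("<vaf_profile>", x$region_id, "-", length(x$vafs), "VAFs,",
      x$G, "mixture components\n")
  cat("  MATH", round(x$math_score, 3), "| TMB", round(x$tmb, 2),
      if (isTRUE(x$high_tmb)) "(high)" else "", "\n")
  if (nrow(x$peaks)) {
    cat("  peaks:", paste(sprintf("%s@%.3f(d=%.2f)", x$peaks$class,
                                  x$peaks$location, x$peaks$density),
                          collapse = ", "), "\n")
  } else cat("  no peaks above the density threshold\n")
  invisible(x)
}
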