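#' Validate a 2x2 contingency table
#' @param table 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts, not all zero.
#' @return The validated integer matrix.
#' @export
as_contingency <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency counts must be non-negative integers")
  }
  if (sum(table) == 0) stop("all-zero contingency table")
  storage.mode(table) <- "integer"
  table
}

.test_result <- function(method, statistic, p_value) {
  structure(list(method = method, statistic = statistic, p_value = p_value),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$method, "| statistic =",
      if (is.na(x$statistic)) "-" else round(x$statistic, 4),
      "| p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass two-sided convention: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins that are at most as
#' probable as the observed one (the convention of `stats::fisher.test`,
#' which reproduces published two-sided values).
#'
#' @param table 2x2 count table (see [as_contingency()]).
#' @return A `test_result` (statistic = conditional odds-ratio estimate).
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as_contingency(table)
  ft <- stats::fisher.test(tab)
  .test_result("fisher_exact", unname(ft$estimate), ft$p.value)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' `X^2 = N (ad - bc)^2 / (r1 r2 c1 c2)` on 1 degree of freedom, without
#' continuity correction by default.
#'
#' @param table 2x2 count table.
#' @param continuity Apply the Yates correction (default `FALSE`).
#' @return A `test_result`.
#' @export
pearson_chi2_2x2 <- function(table, continuity = FALSE) {
  tab <- as_contingency(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a row or column margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  .test_result(if (continuity) "pearson_chi2_yates" else "pearson_chi2",
               unname(ct$statistic), ct$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null enumeration when `length(x) + length(y) <= 12` and the pooled
#' sample has no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Non-empty numeric samples.
#' @return A `test_result` (statistic = U for the first sample) with an
#'   `exact` flag.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  out <- .test_result(if (exact) "mann_whitney_exact" else "mann_whitney_normal",
                      unname(wt$statistic), wt$p.value)
  out$exact <- exact
  out
}

#' Summarize one patient for cohort comparison
#'
#' Runs classification, tree construction with metrics and driver annotation,
#' and per-region VAF profiling, returning the per-patient quantities the
#' cohort report consumes.
#'
#' @param ds A `multiregion_dataset` with >= 2 tumor regions.
#' @param min_vaf,min_alt Presence thresholds (defaults 0.10 and 3).
#' @param metric Distance metric for the tree (default `"hamming_presence"`).
#' @param shape_threshold Public-fraction threshold for the tree shape.
#' @param max_components,density_min,seed Passed to [vaf_profile()].
#' @return Object of class `patient_summary`.
#' @export
summarize_patient <- function(ds, min_vaf = 0.10, min_alt = 3,
                              metric = "hamming_presence",
                              shape_threshold = 0.5,
                              max_components = 5, density_min = 2.0, seed = 1) {
  categories <- classify_mutations(ds, min_vaf, min_alt)
  d <- distance_matrix(ds, metric = metric, min_vaf = min_vaf, min_alt = min_alt)
  tree <- neighbor_joining(d, root_leaf = "normal")
  tree <- tree_metrics(tree, categories, shape_threshold = shape_threshold)
  tree <- annotate_drivers(tree, categories, ds$drivers, ds)
  profiles <- lapply(tumor_regions(ds), function(r) {
    vaf_profile(ds, r, max_components = max_components,
                density_min = density_min, seed = seed)
  })
  names(profiles) <- tumor_regions(ds)
  structure(
    list(patient_id = ds$patient_id,
         categories = categories,
         category_counts = category_counts(categories),
         public_proportion = tree$public_fraction,
         tree = tree,
         shape = tree$shape,
         n_driver_mutations = nrow(tree$driver_placement),
         n_public_driver_mutations = sum(tree$driver_placement$placement == "trunk"),
         profiles = profiles,
         math_scores = vapply(profiles, `[[`, numeric(1), "math_score"),
         neutral_tail = vapply(profiles, `[[`, logical(1), "has_neutral_tail")),
    class = "patient_summary")
}

#' Compare two cohorts of per-patient summaries
#'
#' Assembles the four contrasts of the evolutionary comparison:
#' (i) per-patient public-mutation proportions (Mann-Whitney);
#' (ii) public-driver proportions as a pooled 2x2 contingency (Pearson
#' chi-squared); (iii) per-sample neutral-tail presence as a pooled 2x2
#' contingency (Pearson chi-squared); (iv) per-sample MATH scores
#' (Mann-Whitney). Medians, means and counts accompany each test.
#'
#' @param cohort_a,cohort_b Lists (>= 2 each) of [summarize_patient()]
#'   outputs.
#' @param label_a,label_b Cohort display labels.
#' @return Object of class `cohort_comparison`.
#' @export
compare_cohorts <- function(cohort_a, cohort_b,
                            label_a = "cohort_a", label_b = "cohort_b") {
  for (co in list(cohort_a, cohort_b)) {
    if (length(co) < 2) {
      stop("dependency error: cohort comparison requires >= 2 patients per cohort ",
           "with phylogeny and VAF-profile outputs")
    }
    ok <- vapply(co, function(p) inherits(p, "patient_summary") &&
                   !is.null(p$public_proportion) && length(p$math_scores) > 0,
                 logical(1))
    if (!all(ok)) {
      stop("dependency error: patient summaries are missing phylogeny or ",
           "VAF-profile outputs (stage: summarize_patient)")
    }
  }
  pub_a <- vapply(cohort_a, `[[`, numeric(1), "public_proportion")
  pub_b <- vapply(cohort_b, `[[`, numeric(1), "public_proportion")
  math_a <- unlist(lapply(cohort_a, `[[`, "math_scores"))
  math_b <- unlist(lapply(cohort_b, `[[`, "math_scores"))
  nt_a <- unlist(lapply(cohort_a, `[[`, "neutral_tail"))
  nt_b <- unlist(lapply(cohort_b, `[[`, "neutral_tail"))
  drv_a <- c(sum(vapply(cohort_a, `[[`, numeric(1), "n_public_driver_mutations")),
             sum(vapply(cohort_a, `[[`, numeric(1), "n_driver_mutations")))
  drv_b <- c(sum(vapply(cohort_b, `[[`, numeric(1), "n_public_driver_mutations")),
             sum(vapply(cohort_b, `[[`, numeric(1), "n_driver_mutations")))

  drv_tab <- matrix(c(drv_a[1], drv_a[2] - drv_a[1],
                      drv_b[1], drv_b[2] - drv_b[1]), 2, 2, byrow = TRUE,
                    dimnames = list(c(label_a, label_b), c("public", "non_public")))
  nt_tab <- matrix(c(sum(nt_a), sum(!nt_a), sum(nt_b), sum(!nt_b)),
                   2, 2, byrow = TRUE,
                   dimnames = list(c(label_a, label_b), c("tail", "no_tail")))

  structure(
    list(labels = c(label_a, label_b),
         n_patients = c(length(cohort_a), length(cohort_b)),
         n_samples = c(length(nt_a), length(nt_b)),
         public_proportion = list(
           test = mann_whitney_u(pub_a, pub_b),
           median = c(stats::median(pub_a), stats::median(pub_b)),
           mean = c(mean(pub_a), mean(pub_b))),
         public_drivers = list(
           table = drv_tab,
           test = if (all(colSums(drv_tab) > 0) && all(rowSums(drv_tab) > 0))
             pearson_chi2_2x2(drv_tab) else NULL,
           proportion = c(drv_a[1] / drv_a[2], drv_b[1] / drv_b[2])),
         neutral_tail = list(
           table = nt_tab,
           test = if (all(colSums(nt_tab) > 0) && all(rowSums(nt_tab) > 0))
             pearson_chi2_2x2(nt_tab) else NULL,
           frequency = c(mean(nt_a), mean(nt_b))),
         math = list(
           test = mann_whitney_u(math_a, math_b),
           median = c(stats::median(math_a), stats::median(math_b)),
           mean = c(mean(math_a), mean(math_b)))),
    class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  l <- x$labels
  cat("<cohort_comparison>", l[1], sprintf("(n=%d patients, %d samples)", x$n_patients[1], x$n_samples[1]),
      "vs", l[2], sprintf("(n=%d patients, %d samples)", x$n_patients[2], x$n_samples[2]), "\n")
  cat(sprintf("  public proportion: median %.3f vs %.3f, MW p = %.4g\n",
              x$public_proportion$median[1], x$public_proportion$median[2],
              x$public_proportion$test$p_value))
  cat(sprintf("  public drivers:    %.1f%% vs %.1f%%%s\n",
              100 * x$public_drivers$proportion[1], 100 * x$public_drivers$proportion[2],
              if (!is.null(x$public_drivers$test))
                sprintf(", chi2 p = %.4g", x$public_drivers$test$p_value) else ""))
  cat(sprintf("  neutral tails:     %.1f%% vs %.1f%% of samples%s\n",
              100 * x$neutral_tail$frequency[1], 100 * x$neutral_tail$frequency[2],
              if (!is.null(x$neutral_tail$test))
                sprintf(", chi2 p = %.4g", x$neutral_tail$test$p_value) else ""))
  cat(sprintf("  MATH:              median %.3f vs %.3f, MW p = %.4g\n",
              x$math$median[1], x$math$median[2], x$math$test$p_value))
  invisible(x)
}

#' Flatten a cohort comparison to a summary data frame
#' @param comparison A `cohort_comparison`.
#' @return Data frame with one row per contrast.
#' @export
comparison_table <- function(comparison) {
  x <- comparison
  data.frame(
    contrast = c("public_proportion", "public_drivers", "neutral_tail", "math"),
    method = c(x$public_proportion$test$method,
               if (is.null(x$public_drivers$test)) NA else x$public_drivers$test$method,
               if (is.null(x$neutral_tail$test)) NA else x$neutral_tail$test$method,
               x$math$test$method),
    value_a = c(x$public_proportion$median[1], x$public_drivers$proportion[1],
                x$neutral_tail$frequency[1], x$math$median[1]),
    value_b = c(x$public_proportion$median[2], x$public_drivers$proportion[2],
                x$neutral_tail$frequency[2], x$math$median[2]),
    p_value = c(x$public_proportion$test$p_value,
                if (is.null(x$public_drivers$test)) NA else x$public_drivers$test$p_value,
                if (is.null(x$neutral_tail$test)) NA else x$neutral_tail$test$p_value,
                x$math$test$p_value),
    stringsAsFactors = FALSE)
}
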