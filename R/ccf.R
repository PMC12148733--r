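#' Variant allele frequency from read counts
#'
#' @param alt_count,ref_count Non-negative integer vectors (recycled).
#' @return `alt / (alt + ref)`, in `[0, 1]`.
#' @export
vaf <- function(alt_count, ref_count) {
  if (any(alt_count < 0) || any(ref_count < 0)) stop("read counts must be non-negative")
  tot <- alt_count + ref_count
  if (any(tot == 0)) stop("undefined VAF: zero total depth")
  alt_count / tot
}

#' Point estimate of cancer cell fraction from a VAF
#'
#' Standard purity/copy-number adjustment for a mutation at multiplicity `m`
#' on a segment with tumor total copy number `total_cn` in a sample of the
#' given purity:
#' \deqn{CCF = VAF \times \frac{purity \cdot total\_cn + (1 - purity) \cdot normal\_cn}{purity \cdot m}}
#' capped at `cap` (default 1; a cap of 1.5 can be useful when studying LOH).
#'
#' @param vaf VAF in `[0, 1]`.
#' @param purity Tumor purity in (0, 1].
#' @param total_cn Tumor total copy number at the site (default 2).
#' @param normal_cn Normal copy number (default 2).
#' @param multiplicity Mutation multiplicity, >= 1 and <= `total_cn`.
#' @param cap Upper cap on the returned CCF (default 1).
#' @return CCF estimate in `[0, cap]`.
#' @export
ccf_point <- function(vaf, purity, total_cn = 2, normal_cn = 2,
                      multiplicity = 1, cap = 1.0) {
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  if (any(total_cn < multiplicity)) stop("total_cn must be >= multiplicity")
  pmin(vaf * (purity * total_cn + (1 - purity) * normal_cn) /
         (purity * multiplicity), cap)
}

#' Per-region CCF matrix of a dataset
#'
#' Applies [ccf_point()] entrywise with each tumor region's purity. Without
#' copy-number segments all sites are treated as diploid heterozygous
#' (`total_cn = 2`, multiplicity 1). Absent entries yield `absent_value`
#' (default 0, the convention used for distance computation).
#'
#' @param ds A `multiregion_dataset`.
#' @param cap CCF cap (default 1).
#' @param absent_value Value for absent (unreported) entries.
#' @return Numeric matrix, mutations x tumor regions.
#' @export
ccf_matrix <- function(ds, cap = 1.0, absent_value = 0) {
  v <- vaf_matrix(ds)
  pur <- tumor_purity(ds)
  out <- sweep(v, 2, pur, function(vv, p) ccf_point(vv, p, cap = cap))
  out[is.na(out)] <- absent_value
  out
}

#' Cluster mutations into CCF clusters with a binomial mixture model
#'
#' Expectation-maximization over a mixture in which mutation `i` in region `r`
#' contributes `Binomial(alt_ir; depth_ir, purity_r * phi_kr / 2)` under
#' cluster `k`, where `phi_kr` is the cluster's CCF in region `r` (diploid
#' heterozygous model). The number of clusters is chosen by minimum BIC over
#' `K = 1..max_clusters`, taking the best of `restarts` seed-controlled random
#' initializations per `K` (centers drawn from the empirical CCF quantiles).
#' Mutations absent in a region contribute nothing to the likelihood there.
#' Empty clusters (no mutation assigned at the posterior mode) are dropped.
#'
#' @param ds A `multiregion_dataset` with >= 2 mutations.
#' @param max_clusters Maximum cluster count searched (default 40).
#' @param restarts Random restarts per candidate `K` (default 100).
#' @param seed Integer seed controlling initialization.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap per restart (default 500); restarts that
#'   hit the cap return their best-so-far fit with `converged = FALSE`.
#' @param cap CCF cap (default 1).
#' @return An object of class `ccf_clustering`: `n_clusters`, `assignment`
#'   (named integer vector), `centers` (cluster x region CCF matrix),
#'   `weights`, `log_likelihood`, `model_score` (BIC of the selected model),
#'   `restarts_used`, `converged`, and the per-K search table `search`.
#' @export
fit_binomial_mixture <- function(ds, max_clusters = 40, restarts = 100,
                                 seed = 1, tol = 1e-6, max_iter = 500,
                                 cap = 1.0) {
  alt <- ds$alt
  n <- nrow(alt)
  if (n < 2) stop("at least 2 mutations are required for clustering")
  tot <- alt + ds$ref
  pur <- tumor_purity(ds)
  mask <- !is.na(alt) & tot > 0
  alt[!mask] <- 0L
  tot[!mask] <- 0L
  emp <- ccf_matrix(ds, cap = cap)
  R <- ncol(alt)

  set.seed(seed)
  kmax <- min(max_clusters, n)
  best <- NULL
  search <- data.frame(K = integer(0), log_likelihood = numeric(0), bic = numeric(0))
  for (K in seq_len(kmax)) {
    bestK <- NULL
    for (rep in seq_len(restarts)) {
      init <- .init_centers(emp, K, cap)
      fit <- .em_binmix(alt, tot, pur, init, tol = tol, max_iter = max_iter, cap = cap)
      if (is.null(bestK) || fit$loglik > bestK$loglik) bestK <- fit
      if (K == 1) break  # K = 1 has a closed-form M-step; restarts are identical
    }
    bic <- -2 * bestK$loglik + ((K - 1) + K * R) * log(n)
    search <- rbind(search, data.frame(K = K, log_likelihood = bestK$loglik, bic = bic))
    if (is.null(best) || bic < best$bic) {
      best <- bestK
      best$bic <- bic
      best$K <- K
    }
  }

  # MAP assignments; drop clusters that attract no mutation
  map <- max.col(best$resp, ties.method = "first")
  used <- sort(unique(map))
  relabel <- match(map, used)
  centers <- best$phi[used, , drop = FALSE]
  weights <- best$pi[used] / sum(best$pi[used])
  rownames(centers) <- paste0("C", seq_along(used))
  colnames(centers) <- colnames(alt)

  structure(
    list(n_clusters = length(used),
         assignment = stats::setNames(relabel, rownames(alt)),
         centers = centers,
         weights = weights,
         log_likelihood = best$loglik,
         model_score = best$bic,
         loglik_trace = best$trace,
         restarts_used = if (best$K == 1) 1L else as.integer(restarts),
         converged = best$converged,
         search = search),
    class = "ccf_clustering")
}

#' @export
print.ccf_clustering <- function(x, ...) {
  cat("<ccf_clustering>", x$n_clusters, "clusters over",
      length(x$assignment), "mutations; BIC =", round(x$model_score, 2),
      if (!x$converged) "(EM hit the iteration cap)", "\n")
  print(round(x$centers, 3))
  invisible(x)
}

.init_centers <- function(emp, K, cap) {
  R <- ncol(emp)
  # quantile levels spread over (0,1) with seed-controlled jitter
  q <- (seq_len(K) - 0.5) / K + stats::runif(K, -0.4, 0.4) / K
  q <- pmin(0.999, pmax(0.001, q))
  phi <- vapply(seq_len(R), function(r) stats::quantile(emp[, r], q, names = FALSE),
                numeric(K))
  phi <- matrix(phi, K, R)
  phi <- phi + matrix(stats::runif(K * R, -0.02, 0.02), K, R)
  pmin(pmax(phi, 1e-4), cap)
}

.em_binmix <- function(alt, tot, pur, phi, tol, max_iter, cap) {
  n <- nrow(alt); K <- nrow(phi); R <- ncol(alt)
  pi_k <- rep(1 / K, K)
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  lgamma_const <- lchoose(tot, alt)  # constant across clusters/iterations
  for (it in seq_len(max_iter)) {
    # E-step: log p(mutation i | cluster k)
    lp <- matrix(log(pi_k), n, K, byrow = TRUE)
    for (k in seq_len(K)) {
      p <- pmin(pmax(matrix(pur * phi[k, ] / 2, n, R, byrow = TRUE), 1e-9), 1 - 1e-9)
      ll <- lgamma_const + alt * log(p) + (tot - alt) * log1p(-p)
      lp[, k] <- lp[, k] + rowSums(ll)
    }
    m <- apply(lp, 1, max)
    ll_new <- sum(m + log(rowSums(exp(lp - m))))
    resp <- exp(lp - m)
    resp <- resp / rowSums(resp)
    trace <- c(trace, ll_new)
    if (is.finite(loglik) && abs(ll_new - loglik) <= tol * abs(loglik)) {
      loglik <- ll_new
      converged <- TRUE
      break
    }
    loglik <- ll_new
    # M-step
    pi_k <- pmax(colMeans(resp), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      num <- colSums(resp[, k] * alt)
      den <- colSums(resp[, k] * tot)
      p_hat <- ifelse(den > 0, num / den, 0)
      phi[k, ] <- pmin(cap, pmax(1e-6, 2 * p_hat / pur))
    }
  }
  list(phi = phi, pi = pi_k, resp = resp, loglik = loglik, trace = trace,
       converged = converged)
}
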