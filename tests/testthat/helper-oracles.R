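# Independent brute-force oracles used to check the implementation.

# Fisher exact two-sided p by full enumeration over all tables with the
# observed margins (probability-mass rule).
fisher_oracle <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  pr <- dhyper(xs, r1, N - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, N - r1, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_obs <- sum(outer(x, y, `>`))
  sets <- utils::combn(nx + ny, nx)
  us <- apply(sets, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, `>`))
  })
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Least-squares branch lengths for a fixed 4-leaf unrooted topology ab|cd.
# Returns the fitted pairwise-distance matrix and the residual sum of squares.
ls_fit_quartet <- function(D, split) {
  a <- split[1]; b <- split[2]; c <- split[3]; d <- split[4]
  # parameters: la, lb, lc, ld, internal m; path design over the 6 pairs
  pairs <- rbind(c(a, b), c(a, c), c(a, d), c(b, c), c(b, d), c(c, d))
  X <- matrix(0, 6, 5)
  uses <- list(c(1, 2), c(1, 3, 5), c(1, 4, 5), c(2, 3, 5), c(2, 4, 5), c(3, 4))
  for (i in 1:6) X[i, uses[[i]]] <- 1
  y <- D[pairs]
  beta <- qr.solve(X, y)
  fitted <- X %*% beta
  list(lengths = beta, rss = sum((y - fitted)^2), pairs = pairs, fitted = fitted)
}

# Best quartet topology by exhaustive least squares; returns the split
# (as leaf indices c(a, b, c, d) meaning ab|cd) with minimal RSS.
best_quartet <- function(D) {
  splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  fits <- lapply(splits, ls_fit_quartet, D = D)
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  list(split = splits[[which.min(rss)]], fit = fits[[which.min(rss)]])
}

# Pairwise leaf distances implied by a phylo_tree's edges.
tree_path_dists <- function(tr) {
  phy <- tr$phy
  d <- ape::cophenetic.phylo(phy)
  d[tr$labels, tr$labels]
}
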