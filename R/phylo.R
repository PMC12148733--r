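#' Presence matrix under the calling-floor rule
#'
#' A mutation is present in a region iff it was reported there with
#' `alt_count >= min_alt` and `VAF >= min_vaf`. Absent (unreported) entries
#' are not present.
#'
#' @param ds A `multiregion_dataset`.
#' @param min_vaf Minimum VAF for presence (default 0.10, the calling floor).
#' @param min_alt Minimum alt-read count for presence (default 3).
#' @return Logical matrix, mutations x tumor regions.
#' @export
presence_matrix <- function(ds, min_vaf = 0.10, min_alt = 3) {
  v <- vaf_matrix(ds)
  pres <- !is.na(v) & v >= min_vaf & ds$alt >= min_alt
  pres
}

#' Classify mutations as public, shared or private across regions
#'
#' Public mutations are present in every tumor region, private in exactly one,
#' and shared otherwise (including, by this rule, mutations below the presence
#' thresholds everywhere).
#'
#' @inheritParams presence_matrix
#' @return Named character vector with values `"public"`, `"shared"`,
#'   `"private"`.
#' @export
classify_mutations <- function(ds, min_vaf = 0.10, min_alt = 3) {
  if (length(tumor_regions(ds)) < 2) {
    stop("mutation classification requires at least 2 tumor regions; ",
         "single-region datasets support VAF profiling only")
  }
  pres <- presence_matrix(ds, min_vaf, min_alt)
  n <- rowSums(pres)
  out <- ifelse(n == ncol(pres), "public", ifelse(n == 1L, "private", "shared"))
  stats::setNames(out, rownames(pres))
}

#' Tally of mutation categories
#' @param categories Output of [classify_mutations()].
#' @return Named integer vector with entries public, shared, private.
#' @export
category_counts <- function(categories) {
  vapply(c("public", "shared", "private"),
         function(k) sum(categories == k), integer(1))
}

#' Inter-region distance matrix including the normal pseudo-region
#'
#' `hamming_presence`: number of mutations with discordant presence calls
#' between two regions, the normal having all-absent calls; branch lengths of
#' the resulting tree are then in mutation-count units. `l1_ccf`: sum of
#' absolute per-mutation CCF differences (absent entries count as CCF 0).
#'
#' @inheritParams presence_matrix
#' @param metric `"hamming_presence"` (default) or `"l1_ccf"`.
#' @return Symmetric matrix over tumor regions plus `"normal"`, zero diagonal.
#' @export
distance_matrix <- function(ds, metric = c("hamming_presence", "l1_ccf"),
                            min_vaf = 0.10, min_alt = 3) {
  metric <- match.arg(metric)
  regs <- tumor_regions(ds)
  prof <- switch(metric,
    hamming_presence = cbind(presence_matrix(ds, min_vaf, min_alt) * 1,
                             normal = 0),
    l1_ccf = cbind(ccf_matrix(ds), normal = 0))
  labels <- c(regs, "normal")
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(prof[, i] - prof[, j]))
    }
  }
  d
}

#' Neighbor-joining tree rooted at a chosen leaf
#'
#' Classic Saitou-Nei neighbor joining on a symmetric distance matrix:
#' at each step the pair minimizing the Q-criterion is joined (ties broken by
#' the lowest leaf-index pair in the current matrix order). A negative branch
#' length arising at a join is clamped to 0 and the deficit transferred to its
#' sibling edge, preserving the pair's path length. The unrooted tree is then
#' rooted at `root_leaf` (normally the matched-normal pseudo-region), giving a
#' tree whose trunk is the root leaf's pendant edge.
#'
#' @param dist Symmetric numeric matrix with row/column names; >= 3 leaves.
#' @param root_leaf Leaf name to root at (default `"normal"`).
#' @return An object of class `phylo_tree`: `edges` (data frame
#'   `parent, child, length` in a rooted parent-child orientation, node labels
#'   `I1, I2, ...` for internal nodes), `newick` string, `phy` (an
#'   [ape::read.tree()] object for plotting/export), `root_leaf`,
#'   `trunk_length` and per-leaf `branch_lengths` (root-excluded path lengths
#'   from the first branching node to each leaf).
#' @export
neighbor_joining <- function(dist, root_leaf = "normal") {
  dist <- as.matrix(dist)
  labels <- rownames(dist)
  n <- length(labels)
  if (n < 3) stop("neighbor joining requires at least 3 leaves")
  if (!root_leaf %in% labels) stop("root leaf '", root_leaf, "' not in the matrix")
  if (any(abs(dist - t(dist)) > 1e-9)) stop("distance matrix must be symmetric")

  # node ids: 1..n tips, internals n+1, n+2, ...
  active <- seq_len(n)
  Dm <- dist
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  next_id <- n + 1L
  while (length(active) > 2) {
    m <- length(active)
    rs <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(cand[, 1], cand[, 2])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    li <- Dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- Dm[i, j]; li <- 0 }
    if (lj < 0) { li <- Dm[i, j]; lj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    parent <- c(parent, u, u)
    child <- c(child, active[i], active[j])
    elen <- c(elen, li, lj)
    du <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    active <- c(active[keep], u)
  }
  parent <- c(parent, active[2])
  child <- c(child, active[1])
  elen <- c(elen, max(0, Dm[1, 2]))

  # adjacency of the unrooted tree, then orient away from the root leaf
  n_nodes <- next_id - 1L
  adj <- vector("list", n_nodes)
  wts <- vector("list", n_nodes)
  for (e in seq_along(parent)) {
    a <- parent[e]; b <- child[e]
    adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], elen[e])
    adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], elen[e])
  }
  root <- match(root_leaf, labels)
  node_label <- c(labels, paste0("I", seq_len(n_nodes - n)))
  ep <- integer(0); ec <- integer(0); el <- numeric(0)
  stack <- list(c(root, NA_integer_))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1]; from <- top[2]
    nb <- adj[[v]]; wt <- wts[[v]]
    for (q in seq_along(nb)) {
      if (!is.na(from) && nb[q] == from) next
      ep <- c(ep, v); ec <- c(ec, nb[q]); el <- c(el, wt[q])
      stack[[length(stack) + 1L]] <- c(nb[q], v)
    }
  }
  edges <- data.frame(parent = node_label[ep], child = node_label[ec],
                      length = el, stringsAsFactors = FALSE)

  # emit the root leaf as a zero-length child of the root node so every leaf
  # is a newick tip (the trunk keeps its full length on the tumor side)
  v <- adj[[root]][1]
  newick <- paste0("(", .newick_string(v, root, adj, wts, node_label, n),
                   ":", format(wts[[root]][1], digits = 12), ",",
                   node_label[root], ":0);")
  phy <- ape::read.tree(text = newick)

  tr <- structure(list(edges = edges, newick = newick, phy = phy,
                       root_leaf = root_leaf, labels = labels),
                  class = "phylo_tree")
  tr$trunk_length <- .trunk_length(tr)
  tr$branch_lengths <- .branch_lengths(tr)
  tr
}

.newick_string <- function(v, from, adj, wts, node_label, n_tips) {
  nb <- adj[[v]]; wt <- wts[[v]]
  parts <- character(0)
  for (q in seq_along(nb)) {
    if (!is.na(from) && nb[q] == from) next
    parts <- c(parts, paste0(.newick_string(nb[q], v, adj, wts, node_label, n_tips),
                             ":", format(wt[q], digits = 12)))
  }
  if (!length(parts)) return(node_label[v])
  lab <- if (v <= n_tips) node_label[v] else ""
  paste0("(", paste(parts, collapse = ","), ")", lab)
}

.children <- function(tr, node) tr$edges[tr$edges$parent == node, , drop = FALSE]

.trunk_length <- function(tr) {
  # walk from the root leaf through unary nodes; the trunk ends at the first
  # node with more than one child
  total <- 0
  node <- tr$root_leaf
  repeat {
    ch <- .children(tr, node)
    if (nrow(ch) == 0) return(total)
    if (nrow(ch) > 1) return(total)
    total <- total + ch$length
    node <- ch$child
  }
}

.first_branching_node <- function(tr) {
  node <- tr$root_leaf
  repeat {
    ch <- .children(tr, node)
    if (nrow(ch) != 1) return(node)
    node <- ch$child
  }
}

.branch_lengths <- function(tr) {
  start <- .first_branching_node(tr)
  out <- numeric(0)
  walk <- function(node, acc) {
    ch <- .children(tr, node)
    if (nrow(ch) == 0) {
      out[[node]] <<- acc
      return(invisible())
    }
    for (q in seq_len(nrow(ch))) walk(ch$child[q], acc + ch$length[q])
  }
  walk(start, 0)
  out[setdiff(names(out), tr$root_leaf)]
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat("<phylo_tree> rooted at", x$root_leaf, "with",
      length(x$labels), "leaves; trunk length", round(x$trunk_length, 3), "\n")
  if (!is.null(x$public_fraction)) {
    cat("  public fraction", round(x$public_fraction, 3), "->", x$shape, "\n")
  }
  invisible(x)
}

#' Annotate a tree with trunk/branch structure and its shape class
#'
#' Adds the category tallies, the public-mutation fraction and the tree-shape
#' label: `long_trunk_short_branches` when the public fraction reaches
#' `shape_threshold` (default 0.5, operationalizing "predominance of public
#' mutations"), else `short_trunk_long_branches`.
#'
#' @param tree A `phylo_tree`.
#' @param categories Output of [classify_mutations()].
#' @param shape_threshold Public-fraction threshold for the shape call.
#' @return The tree with fields `category_counts`, `public_fraction`, `shape`.
#' @export
tree_metrics <- function(tree, categories, shape_threshold = 0.5) {
  counts <- category_counts(categories)
  tree$category_counts <- counts
  tree$public_fraction <- unname(counts["public"] / sum(counts))
  tree$shape <- if (tree$public_fraction >= shape_threshold) {
    "long_trunk_short_branches"
  } else {
    "short_trunk_long_branches"
  }
  tree$shape_threshold <- shape_threshold
  tree
}

#' Place driver mutations on the trunk or branches
#'
#' A driver mutation classified public sits on the trunk; any other driver
#' mutation sits on a branch. The proportion of driver mutations that are
#' public is reported alongside the placements.
#'
#' @param tree A `phylo_tree` (typically after [tree_metrics()]).
#' @param categories Output of [classify_mutations()].
#' @param drivers Character vector of driver gene names.
#' @param ds The `multiregion_dataset` the categories came from.
#' @return The tree with fields `driver_placement` (data frame
#'   `mut_id, gene, category, placement`) and `public_driver_proportion`.
#' @export
annotate_drivers <- function(tree, categories, drivers, ds) {
  absent <- setdiff(drivers, ds$mutations$gene)
  if (length(absent)) {
    warning("driver genes absent from the dataset: ", paste(absent, collapse = ", "))
  }
  sel <- which(ds$mutations$gene %in% drivers)
  ids <- mutation_ids(ds)[sel]
  cat_d <- categories[ids]
  placement <- data.frame(
    mut_id = ids,
    gene = ds$mutations$gene[sel],
    category = unname(cat_d),
    placement = ifelse(cat_d == "public", "trunk", "branch"),
    stringsAsFactors = FALSE)
  tree$driver_placement <- placement
  tree$public_driver_proportion <-
    if (nrow(placement)) mean(placement$placement == "trunk") else NA_real_
  tree
}

#' Write a tree to a newick file
#' @param tree A `phylo_tree`.
#' @param path Output path.
#' @return Invisibly, the newick string.
#' @export
write_tree_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(tree$newick)
}
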