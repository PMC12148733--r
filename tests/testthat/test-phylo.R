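test_that("mutations are classified by regional presence", {
  v <- rbind(c(0.4, 0.3, 0.2),    # above threshold everywhere -> public
             c(0.4, 0.0, 0.0),    # one region -> private
             c(0.4, 0.12, 0.0),   # two of three -> shared
             c(0.05, 0.05, 0.05)) # below the floor everywhere -> shared
  ds <- make_vaf_dataset(v, depth = 100)
  cats <- unname(classify_mutations(ds))
  expect_equal(cats, c("public", "private", "shared", "shared"))
  expect_equal(unname(category_counts(classify_mutations(ds))), c(1, 2, 1))
  # min_alt gates presence even above min_vaf: depth 20 gives 0.12 * 20 < 3
  ds2 <- make_vaf_dataset(v, depth = 20)
  expect_equal(unname(classify_mutations(ds2))[3], "private")
  # permutation invariance in region order
  dsr <- make_vaf_dataset(v[, c(3, 1, 2)], depth = 100)
  expect_equal(unname(category_counts(classify_mutations(dsr))),
               unname(category_counts(classify_mutations(ds))))
  # single tumor region unsupported
  ds1 <- make_vaf_dataset(v[, 1, drop = FALSE], depth = 100)
  expect_error(classify_mutations(ds1), "at least 2 tumor regions")
})

test_that("distance matrices count discordant calls and satisfy the metric axioms", {
  # identical presence in R1/R2; R3 empty
  v <- rbind(c(0.4, 0.4, 0), c(0.3, 0.3, 0))
  ds <- make_vaf_dataset(v, depth = 100)
  d <- distance_matrix(ds)
  expect_equal(d["R1", "R2"], 0)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(abs(d - t(d)) < 1e-12))

  # region with 10 private + 5 public vs normal: distance 15
  v2 <- rbind(matrix(rep(c(0.4, 0.4, 0.4), 5), ncol = 3, byrow = TRUE),
              matrix(rep(c(0.4, 0, 0), 10), ncol = 3, byrow = TRUE))
  ds2 <- make_vaf_dataset(v2, depth = 100)
  d2 <- distance_matrix(ds2)
  expect_equal(d2["R1", "normal"], 15)
  expect_equal(d2["R2", "normal"], 5)

  # triangle inequality on random presence/CCF instances
  set.seed(77)
  for (rep in 1:5) {
    v3 <- matrix(runif(60, 0, 0.5), 15, 4)
    v3[v3 < 0.15] <- 0
    ds3 <- make_vaf_dataset(v3, depth = 200)
    for (metric in c("hamming_presence", "l1_ccf")) {
      dd <- distance_matrix(ds3, metric = metric)
      n <- nrow(dd)
      for (i in 1:n) for (j in 1:n) for (k in 1:n) {
        expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-9)
      }
    }
  }
  expect_error(distance_matrix(ds, metric = "euclid"), "arg")
})

test_that("neighbor joining reproduces the additive quartet exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D, root_leaf = "D")
  # oracle: least-squares over all three quartet topologies
  bq <- best_quartet(D)
  expect_equal(bq$split, c(1, 2, 3, 4))            # AB|CD
  expect_equal(unname(bq$fit$lengths), c(1, 2, 3, 4, 1))
  expect_equal(bq$fit$rss, 0, tolerance = 1e-18)
  # the NJ tree realizes the same additive metric exactly
  expect_equal(tree_path_dists(tr), D, tolerance = 1e-9)
  expect_equal(tr$trunk_length, 4)
  # path lengths from the first branching node: A = 1+1, B = 1+2, C = 3
  expect_equal(sort(unname(tr$branch_lengths)), c(2, 3, 3), tolerance = 1e-9)
  expect_error(neighbor_joining(D[1:2, 1:2], "A"), "at least 3 leaves")
})

test_that("three leaves resolve with closed-form lengths", {
  D <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "N"), c("A", "B", "N")))
  tr <- neighbor_joining(D, root_leaf = "N")
  # a + b = 5, a + c = 9, b + c = 10 -> a = 2, b = 3, c = 7
  expect_equal(tree_path_dists(tr), D, tolerance = 1e-9)
  expect_equal(tr$trunk_length, 7)
})

test_that("NJ recovers random additive trees exactly and matches ape", {
  set.seed(101)
  for (n_leaves in c(4, 5, 6)) {
    for (rep in 1:3) {
      phy <- ape::rtree(n_leaves, br = function(k) sample(1:20, k, replace = TRUE))
      D <- ape::cophenetic.phylo(phy)
      D <- D[sort(rownames(D)), sort(rownames(D))]
      tr <- neighbor_joining(D, root_leaf = rownames(D)[1])
      expect_equal(tree_path_dists(tr)[rownames(D), rownames(D)], D,
                   tolerance = 1e-8)
      # independent route: ape's NJ yields the same unrooted topology
      expect_equal(ape::dist.topo(ape::unroot(tr$phy), ape::unroot(ape::nj(D))), 0,
                   ignore_attr = TRUE)
    }
  }
})

test_that("rooted topology is invariant to leaf order", {
  set.seed(55)
  phy <- ape::rtree(5, br = function(k) sample(1:9, k, replace = TRUE))
  D <- ape::cophenetic.phylo(phy)
  perm <- sample(nrow(D))
  tr1 <- neighbor_joining(D, root_leaf = "t1")
  tr2 <- neighbor_joining(D[perm, perm], root_leaf = "t1")
  expect_equal(ape::dist.topo(ape::unroot(tr1$phy), ape::unroot(tr2$phy)), 0,
               ignore_attr = TRUE)
  expect_equal(tr1$trunk_length, tr2$trunk_length, tolerance = 1e-9)
})

test_that("noise-free simulated trees put all public mutations on the trunk", {
  for (sd in c(41, 42)) {
    sim <- simulate_patient("continuous_selection", n_regions = 5, seed = sd)
    ds <- expected_counts_dataset(sim, depth = 2000)
    cats <- classify_mutations(ds)
    d <- distance_matrix(ds)
    tr <- neighbor_joining(d, root_leaf = "normal")
    expect_equal(tr$trunk_length, unname(category_counts(cats)["public"]))
    # the planted trunk mutations are all classified public
    root_ids <- sim$truth$mutation$mut_id[sim$truth$mutation$clone_id %in% 1]
    expect_true(all(cats[root_ids] == "public"))
  }
})

test_that("tree shape follows the public-mutation fraction", {
  v <- rbind(matrix(rep(c(0.4, 0.4, 0.4), 8), ncol = 3, byrow = TRUE),
             matrix(rep(c(0.4, 0, 0), 2), ncol = 3, byrow = TRUE))
  ds <- make_vaf_dataset(v, depth = 100)
  cats <- classify_mutations(ds)
  tr <- neighbor_joining(distance_matrix(ds), "normal")
  tr <- tree_metrics(tr, cats)
  expect_equal(tr$public_fraction, 0.8)
  expect_equal(tr$shape, "long_trunk_short_branches")
  # mostly private: shape flips
  v2 <- v[c(1, 2, rep(9:10, 4)), ]
  ds2 <- make_vaf_dataset(v2, depth = 100)
  tr2 <- tree_metrics(neighbor_joining(distance_matrix(ds2), "normal"),
                      classify_mutations(ds2))
  expect_equal(tr2$public_fraction, 0.2)
  expect_equal(tr2$shape, "short_trunk_long_branches")
})

test_that("driver mutations map to trunk or branch with their proportion", {
  # 10 drivers: 9 public, 1 private
  v <- rbind(matrix(rep(c(0.4, 0.4, 0.4), 9), ncol = 3, byrow = TRUE),
             c(0.4, 0, 0))
  ds <- make_vaf_dataset(v, depth = 100)
  ds$mutations$gene <- paste0("G", 1:10)
  ds$mutations$is_driver <- TRUE
  ds$drivers <- ds$mutations$gene
  rn <- mutation_ids(ds)
  cats <- classify_mutations(ds)
  tr <- tree_metrics(neighbor_joining(distance_matrix(ds), "normal"), cats)
  tr <- annotate_drivers(tr, cats, ds$drivers, ds)
  expect_equal(nrow(tr$driver_placement), 10)
  expect_equal(sum(tr$driver_placement$placement == "trunk"), 9)
  expect_equal(tr$public_driver_proportion, 0.9)
  expect_warning(annotate_drivers(tr, cats, c(ds$drivers, "NOPE"), ds),
                 "absent from the dataset")
})
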