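test_that("simulation is deterministic in the seed", {
  a <- simulate_patient("continuous_selection", n_regions = 4, seed = 11)
  b <- simulate_patient("continuous_selection", n_regions = 4, seed = 11)
  expect_identical(a$dataset$alt, b$dataset$alt)
  expect_identical(a$truth$true_ccf, b$truth$true_ccf)
  c1 <- simulate_cohort("selection_then_neutral", 3, seed = 5)
  c2 <- simulate_cohort("selection_then_neutral", 3, seed = 5)
  expect_identical(lapply(c1, function(p) p$dataset$alt),
                   lapply(c2, function(p) p$dataset$alt))
})

test_that("single-clone limit yields all-public mutations at VAF 1/2", {
  sim <- simulate_patient("continuous_selection", n_regions = 3, depth = 200,
                          purity = 1, n_subclones = 0, n_subclonal = 0,
                          n_neutral = 0, n_trunk = 100, seed = 3)
  expect_true(all(sim$truth$mutation$true_category == "public"))
  v <- vaf_matrix(sim$dataset)
  se <- sqrt(0.25 / 200) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.5), 3 * se)
  cats <- classify_mutations(sim$dataset)
  expect_true(all(cats == "public"))
})

test_that("neutral-class mutations land in the low-VAF tail", {
  sim <- simulate_patient("selection_then_neutral", n_regions = 4, depth = 200,
                          purity = 1, n_neutral = 500, seed = 9)
  truth <- sim$truth
  neut <- which(truth$mutation$is_neutral)
  # VAF observed in the single region each neutral mutation occupies
  reg <- apply(truth$true_ccf[neut, ] > 0, 1, which)
  v <- vaf_matrix(sim$dataset)[cbind(neut, reg)]
  frac_low <- mean(v < 0.15, na.rm = TRUE)
  # oracle: E_c~U(0,0.2) P(Binom(200, c/2) <= 29) by numerical integration
  cs <- seq(0.0005, 0.1995, by = 0.001)
  oracle <- mean(pbinom(ceiling(0.15 * 200) - 1, 200, cs / 2))
  expect_gte(frac_low, 0.80)
  expect_lt(abs(frac_low - oracle), 3 * sqrt(oracle * (1 - oracle) / length(neut)) + 0.01)
})

test_that("true CCFs equal sums of carrying-clone fractions (infinite sites)", {
  sim <- simulate_patient("continuous_selection", n_regions = 5, seed = 21)
  truth <- sim$truth
  expect_false(anyDuplicated(truth$mutation$mut_id) > 0)
  parent <- truth$clone_tree$parent_id
  anc <- lapply(seq_along(parent), function(cl) {
    p <- cl
    while (!is.na(parent[p[1]])) p <- c(parent[p[1]], p)
    p
  })
  clone_borne <- which(!truth$mutation$is_neutral)
  for (i in sample(clone_borne, 20)) {
    cl <- truth$mutation$clone_id[i]
    carriers <- which(vapply(anc, function(p) cl %in% p, logical(1)))
    expect_equal(unname(truth$true_ccf[i, ]),
                 unname(colSums(truth$clone_fractions[carriers, , drop = FALSE])),
                 tolerance = 1e-9)
  }
  # root-clone mutations are public
  root_muts <- truth$mutation$clone_id == 1 & !truth$mutation$is_neutral
  expect_true(all(truth$mutation$true_category[root_muts] == "public"))
  # per-region clone fractions sum to 1
  expect_equal(unname(colSums(truth$clone_fractions)),
               rep(1, ncol(truth$clone_fractions)), tolerance = 1e-9)
})

test_that("observed VAF means converge to purity * CCF / 2 at high depth", {
  sim <- simulate_patient("continuous_selection", n_regions = 3, depth = 10000,
                          purity = 0.8, seed = 13)
  evaf <- sweep(sim$truth$true_ccf / 2, 2, sim$truth$purity, `*`)
  v <- vaf_matrix(sim$dataset)
  keep <- evaf > 0.01
  expect_lt(abs(mean(v[keep]) / mean(evaf[keep]) - 1), 0.01)
})

test_that("classifier recovers threshold-consistent truth categories at depth 2000", {
  agree <- vapply(c(31, 32), function(sd) {
    sim <- simulate_patient("selection_then_neutral", n_regions = 5,
                            depth = 2000, seed = sd)
    cats <- classify_mutations(sim$dataset)
    truth <- truth_categories(sim$truth, depth = 2000)
    mean(cats[names(truth)] == truth)
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})

test_that("cohort simulation draws 3-7 regions and respects overrides", {
  co <- simulate_cohort("continuous_selection", 8, seed = 2,
                        overrides = list(depth = 150))
  expect_length(co, 8)
  nreg <- vapply(co, function(p) length(tumor_regions(p$dataset)), integer(1))
  expect_true(all(nreg >= 3 & nreg <= 7))
  expect_true(all(vapply(co, function(p)
    all(p$dataset$regions$mean_depth[p$dataset$regions$layer != "normal"] == 150),
    logical(1))))
  ids <- vapply(co, function(p) p$dataset$patient_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("impossible clone budgets raise configuration errors", {
  expect_error(simulate_patient("continuous_selection", n_subclones = 5,
                                n_subclonal = 3, seed = 1),
               "configuration error")
  expect_error(simulate_patient("continuous_selection", n_subclones = 0,
                                n_subclonal = 10, seed = 1),
               "configuration error")
})
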