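write_toy_tables <- function(dir) {
  # 3 tumor regions, 5 mutations; m5 absent from R2/R3, m4 covered-zero in R3
  tab <- data.frame(
    patient = "P1",
    region = c(rep("R1", 5), rep("R2", 4), rep("R3", 4)),
    chrom = c("chr1", "chr1", "chr2", "chr3", "chr4",
              "chr1", "chr1", "chr2", "chr3",
              "chr1", "chr1", "chr2", "chr3"),
    pos = c(101, 202, 303, 404, 505, 101, 202, 303, 404, 101, 202, 303, 404),
    ref = "A", alt = "T",
    alt_count = c(40, 35, 20, 12, 30, 42, 30, 0, 15, 38, 28, 22, 0),
    ref_count = c(60, 65, 80, 88, 70, 58, 70, 100, 85, 62, 72, 78, 100),
    gene = c("TP53", "APC", "", "KRAS", "", "TP53", "APC", "", "KRAS",
             "TP53", "APC", "", "KRAS"),
    is_driver = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                  TRUE, TRUE, FALSE, TRUE))
  man <- data.frame(
    patient_id = "P1",
    region_id = c("R1", "R2", "R3", "N1"),
    purity = c(0.8, 0.6, 0.7, 1),
    mean_depth = c(200, 200, 200, 100),
    layer = c("surface", "deep", "surface", "normal"),
    msi_score = c(0.4, 0.2, 0.9, NA),
    callable_mb = 35)
  tp <- file.path(dir, "muts.tsv"); mp <- file.path(dir, "manifest.tsv")
  write.table(tab, tp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  list(table = tp, manifest = mp, raw = tab, man = man)
}

test_that("a toy table loads into a validated dataset", {
  td <- withr::local_tempdir()
  fx <- write_toy_tables(td)
  ds <- read_mutation_table(fx$table, fx$manifest)
  expect_s3_class(ds, "multiregion_dataset")
  expect_equal(n_mutations(ds), 5)
  expect_equal(tumor_regions(ds), c("R1", "R2", "R3"))
  expect_equal(unname(tumor_purity(ds)), c(0.8, 0.6, 0.7))
  # absent vs covered-with-zero-alt are distinct
  expect_true(is.na(ds$alt["chr4:505:A:T", "R2"]))          # never reported
  expect_identical(ds$alt["chr2:303:A:T", "R2"], 0L)        # covered, zero alt
  expect_identical(ds$ref["chr2:303:A:T", "R2"], 100L)
  expect_setequal(ds$drivers, c("TP53", "APC", "KRAS"))
})

test_that("round-trip write then read reproduces counts and missingness", {
  td <- withr::local_tempdir()
  fx <- write_toy_tables(td)
  ds <- read_mutation_table(fx$table, fx$manifest)
  write_mutation_table(ds, file.path(td, "out.tsv"), file.path(td, "out_man.tsv"))
  ds2 <- read_mutation_table(file.path(td, "out.tsv"), file.path(td, "out_man.tsv"))
  expect_identical(ds2$alt, ds$alt)
  expect_identical(ds2$ref, ds$ref)
  expect_equal(ds2$regions$purity, ds$regions$purity)
  expect_equal(mutation_ids(ds2), mutation_ids(ds))
  # the absent entry is still NA, the zero-alt entry still 0
  expect_true(is.na(ds2$alt["chr4:505:A:T", "R2"]))
  expect_identical(ds2$alt["chr2:303:A:T", "R2"], 0L)
})

test_that("malformed and inconsistent inputs are rejected with clear errors", {
  td <- withr::local_tempdir()
  fx <- write_toy_tables(td)

  # region absent from the manifest
  bad <- fx$raw; bad$region[1] <- "R9"
  bp <- file.path(td, "bad1.tsv")
  write.table(bad, bp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  expect_error(read_mutation_table(bp, fx$manifest), "absent from the manifest")

  # duplicated (mutation, region) row
  bad <- rbind(fx$raw, fx$raw[1, ])
  write.table(bad, bp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  expect_error(read_mutation_table(bp, fx$manifest), "duplicate mutation row at line")

  # malformed count names the line
  bad <- fx$raw; bad$alt_count <- as.character(bad$alt_count); bad$alt_count[3] <- "x"
  write.table(bad, bp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  expect_error(read_mutation_table(bp, fx$manifest), "line 4")

  # patient mismatch between table and manifest
  bad <- fx$raw; bad$patient <- "P2"
  write.table(bad, bp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  expect_error(read_mutation_table(bp, fx$manifest), "patient mismatch")

  # manifest must have exactly one normal
  man2 <- read.delim(fx$manifest, na.strings = ".")
  man2$layer[4] <- "deep"
  mp2 <- file.path(td, "man2.tsv")
  write.table(man2, mp2, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  expect_error(read_mutation_table(fx$table, mp2), "exactly one region")
})

test_that("zero-depth covered records are flagged, not silently used", {
  alt <- matrix(c(5L, 0L, 6L, 4L), 2, 2)
  ref <- matrix(c(95L, 0L, 94L, 96L), 2, 2)
  expect_warning(ds <- make_counts_dataset(alt, ref), "zero total depth")
  expect_true(ds$zero_depth[2, 1])
  expect_true(is.na(vaf_matrix(ds)[2, 1]))
})

test_that("copy-number segments validate 1-based inclusive coordinates", {
  td <- withr::local_tempdir()
  seg <- data.frame(chrom = "chr1", start = c(1, 500), end = c(400, 900),
                    total_cn = c(2, 3), minor_cn = c(1, 1))
  sp <- file.path(td, "cn.tsv")
  write.table(seg, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_cn_segments(sp)$total_cn, c(2, 3))
  seg$minor_cn[1] <- 3
  write.table(seg, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cn_segments(sp), "minor_cn")
})

test_that("driver selection intersects both methods with strict alpha", {
  a <- c(TP53 = 0.001, APC = 0.2)
  b <- c(TP53 = 0.01, APC = 0.01)
  expect_equal(select_drivers(a, b), "TP53")
  # disjoint significant sets
  expect_length(select_drivers(c(G1 = 0.01, G2 = 0.5), c(G1 = 0.5, G2 = 0.01)), 0)
  # boundary: p exactly alpha is excluded
  expect_length(select_drivers(c(G1 = 0.05), c(G1 = 0.001)), 0)
  expect_error(select_drivers(c(G1 = 1.2), c(G1 = 0.01)), "\\[0, 1\\]")
})
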