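test_that("generation is deterministic given the seed and differs across seeds", {
  dir1 <- file.path(tempdir(), "det_a")
  dir2 <- file.path(tempdir(), "det_b")
  dir3 <- file.path(tempdir(), "det_c")
  cfg <- simulationConfig(seed = 33, n_patients = 4L, n_genes = 10L,
                          n_common = 40L, n_somatic = 30L,
                          double_hit_count = 2L, decoys_per_criterion = 1L)
  simulateCohort(cfg, dir1)
  simulateCohort(cfg, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  f2 <- list.files(dir2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(dir1, f))),
                 unname(tools::md5sum(file.path(dir2, f))), info = f)
  ## a different seed moves the planted variant positions
  cfg2 <- cfg; cfg2$seed <- 34L
  simulateCohort(cfg2, dir3)
  t1 <- read.delim(file.path(dir1, "truth", "private.tsv"))
  t3 <- read.delim(file.path(dir3, "truth", "private.tsv"))
  expect_false(setequal(paste(t1$chrom, t1$pos), paste(t3$chrom, t3$pos)))
})

test_that("a fresh bundle passes verification; tampering is caught and named", {
  b <- cachedBundle("small", smallConfig())
  report <- verifyTruth(b)
  expect_true(all(report$n >= 0))
  expect_setequal(report$check,
                  c("planted_variants_present", "no_unaccounted_variants",
                    "decoy_annotations_consistent", "double_hits_supported",
                    "exposure_weights_sum_to_1"))
  ## copy the bundle, drop one truth row: verification must fail naming it
  tdir <- copyBundle(b, "tampered")
  priv_path <- file.path(tdir, "truth", "private.tsv")
  tr <- read.delim(priv_path)
  write.table(tr[-1, ], priv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(verifyTruth(tdir), "unaccounted")
  ## a corrupted zygosity is also caught
  tr2 <- read.delim(priv_path)
  tr2$zygosity[1] <- if (tr2$zygosity[1] == "het") "hom_alt" else "het"
  write.table(tr2, priv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(verifyTruth(tdir), "zygosity mismatch")
})

test_that("planted carrier counts stay inside binomial bounds of the configured rates", {
  b <- noiselessBundle()
  cfg <- bundleConfig(b)
  tr <- bundleTruth(b)
  carriers <- tr$gene_carriers
  n <- cfg$n_patients
  p_carrier <- 1 - exp(-cfg$private_rate)   # Poisson(rate) > 0
  for (i in seq_along(p_carrier)) {
    lim <- qbinom(c(0.0005, 0.9995), n, p_carrier[i])
    cnt <- carriers$carrier_count[i]
    expect_gte(cnt, lim[1])
    expect_lte(cnt, lim[2])
  }
  ## the flagship and CDH1-like genes sit near their configured fractions
  expect_gt(carriers$carrier_count[1], 2)
  expect_lt(carriers$carrier_count[8], qbinom(0.9995, n, p_carrier[8]) + 1)
})

test_that("decoy variants violate exactly one criterion each", {
  b <- cachedBundle("small", smallConfig())
  tr <- bundleTruth(b)$private
  dec <- tr[tr$role != "private", ]
  flags <- as.matrix(dec[, c("c1_consequence", "c2_het", "c3_rare",
                             "c4_singleton", "c5_mappable", "c6_unique")])
  expect_true(all(rowSums(!flags) == 1))
  expect_false(any(dec$is_private))
  ## the violated criterion matches the decoy's role label
  violated <- apply(!flags, 1, which)
  expect_equal(paste0("decoy_c", violated), dec$role)
})

test_that("a zero double-hit configuration yields zero events end to end", {
  dir <- file.path(tempdir(), "no_dh")
  cfg <- simulationConfig(seed = 55, n_patients = 4L, n_genes = 10L,
                          n_common = 40L, n_somatic = 20L,
                          double_hit_count = 0L, loh_extra_per_tumor = 0L,
                          decoys_per_criterion = 0L, read_noise = FALSE)
  b <- simulateCohort(cfg, dir)
  expect_equal(nrow(bundleTruth(b)$double_hits), 0)
  out <- file.path(tempdir(), "no_dh_out")
  res <- suppressMessages(suppressWarnings(runPipeline(dir, out)))
  expect_equal(nrow(doubleHitEvents(res$double_hits)), 0)
})

test_that("the criterion panel has 4 passes and 20 single-violation decoys", {
  panel <- makeCriterionPanel()
  expect_equal(nrow(panel), 24)
  expect_equal(sum(panel$exp_private), 4)
  exp_flags <- as.matrix(panel[, paste0("exp_c", 1:6)])
  expect_true(all(rowSums(!exp_flags[!panel$exp_private, ]) == 1))
})
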