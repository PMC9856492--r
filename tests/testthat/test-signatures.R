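test_that("context categories are pyrimidine-centric and strand-involutive", {
  seqstr <- "AACAGTGATTCGGCTA"
  ref <- Biostrings::DNAStringSet(seqstr); names(ref) <- "c"
  ## A[C>A]A at position 3
  i <- contextCategory("c", 3, "C", "A", ref)
  expect_equal(names(i), "A[C>A]A")
  expect_equal(unname(i), match("A[C>A]A", sbs96Categories()))
  ## G>T with context T,G,A folds to T[C>A]A
  expect_equal(substr(seqstr, 6, 8), "TGA")
  j <- contextCategory("c", 7, "G", "T", ref)
  expect_equal(names(j), "T[C>A]A")
  ## involution: the reverse-complemented variant gives the same category
  rc <- Biostrings::DNAStringSet(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqstr))))
  names(rc) <- "c"
  L <- nchar(seqstr)
  j2 <- contextCategory("c", L - 7 + 1, "C", "A", rc)
  expect_equal(unname(j2), unname(j))
  expect_error(contextCategory("c", 3, "CA", "A", ref), "SNVs only")
  expect_error(contextCategory("c", 3, "G", "A", ref), "mismatch")
})

test_that("catalogs conserve the SNV count and order categories canonically", {
  set.seed(8)
  seqstr <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(seqstr); names(ref) <- "c"
  pos <- sample(2:2999, 400)
  refb <- vapply(pos, function(p) substr(seqstr, p, p), character(1))
  altb <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1), character(1))
  snvs <- data.frame(sample_id = sample(c("S1", "S2"), 400, TRUE),
                     chrom = "c", pos = pos, ref = refb, alt = altb)
  cat <- buildCatalog(snvs, ref, c("S1", "S2", "S3"))
  m <- catalogCounts(cat)
  expect_equal(sum(m), 400)
  expect_equal(rownames(m), c("S1", "S2", "S3"))
  expect_equal(colnames(m), sbs96Categories())
  expect_equal(sum(m["S3", ]), 0)
  expect_equal(length(sbs96Categories()), 96)
  expect_false(anyDuplicated(sbs96Categories()) > 0)
})

test_that("toy signatures are valid and mutually dissimilar", {
  sigs <- toySignatures()
  p <- signatureProbs(sigs)
  expect_equal(unname(colSums(p)), rep(1, 3))
  cs <- combn(3, 2, function(ij)
    sum(p[, ij[1]] * p[, ij[2]]) /
      sqrt(sum(p[, ij[1]]^2) * sum(p[, ij[2]]^2)))
  expect_true(all(cs <= 0.2))
  ## TSV round trip
  tmp <- withr::local_tempfile()
  writeSignatureMatrix(sigs, tmp)
  back <- readSignatureMatrix(tmp)
  expect_equal(signatureProbs(back), p, tolerance = 1e-12)
})

test_that("a catalog inside the signature span refits exactly", {
  sigs <- toySignatures()
  p <- signatureProbs(sigs)
  counts <- matrix(as.integer(round(1e6 * p[, "sigB"])), nrow = 1,
                   dimnames = list("S1", sbs96Categories()))
  expo <- fitExposures(new("MutationCatalog", counts = counts), sigs)
  w <- exposureWeights(expo)
  expect_equal(unname(w[1, "sigB"]), 1, tolerance = 1e-4)
  expect_equal(unname(reconstructionCosine(expo)), 1, tolerance = 1e-6)
  expect_equal(unname(dominantSignature(expo)), "sigB")
})

test_that("planted Dirichlet mixtures are recovered within tolerance", {
  set.seed(2024)
  sigs <- toySignatures()
  S <- signatureProbs(sigs)
  n_samples <- 20
  truth <- t(vapply(seq_len(n_samples), function(i) {
    g <- rgamma(3, 1); g / sum(g)
  }, numeric(3)))
  counts <- t(vapply(seq_len(n_samples), function(i)
    as.integer(rmultinom(1, 5000, S %*% truth[i, ])), integer(96)))
  dimnames(counts) <- list(sprintf("S%02d", seq_len(n_samples)),
                           sbs96Categories())
  expo <- fitExposures(new("MutationCatalog", counts = counts), sigs)
  mae <- mean(abs(exposureWeights(expo) - truth))
  expect_lte(mae, 0.03)
  ## the documented two-signature example stays within +/- 0.05
  c2 <- as.integer(rmultinom(1, 2000, 0.6 * S[, "sigA"] + 0.4 * S[, "sigC"]))
  counts2 <- matrix(c2, nrow = 1, dimnames = list("M", sbs96Categories()))
  w2 <- exposureWeights(fitExposures(new("MutationCatalog",
                                         counts = counts2), sigs))
  expect_equal(unname(w2[1, "sigA"]), 0.6, tolerance = 0.05 / 0.6)
  expect_equal(unname(w2[1, "sigC"]), 0.4, tolerance = 0.05 / 0.4)
  ## identical samples give identical exposures
  dup <- rbind(counts[1, , drop = FALSE], counts[1, , drop = FALSE])
  rownames(dup) <- c("A", "B")
  wd <- exposureWeights(fitExposures(new("MutationCatalog", counts = dup),
                                     sigs))
  expect_equal(wd["A", ], wd["B", ])
})

test_that("dominant assignment uses argmax with a lexicographic tie-break", {
  w <- rbind(c(0.3, 0.2, 0.5), c(0.45, 0.45, 0.1), c(0.2, 0.5, 0.3))
  dimnames(w) <- list(c("S1", "S2", "S3"), c("sigA", "sigB", "sigC"))
  expo <- new("ExposureSet", weights = w, cosine = rep(1, 3),
              dominant = c("sigC", "sigA", "sigB"))
  dom <- assignDominant(expo)
  expect_equal(dom$per_sample$dominant, c("sigC", "sigA", "sigB"))
  ## 11 of 186 dominant -> 5.9%
  w186 <- matrix(rep(c(0.6, 0.3, 0.1), each = 186), ncol = 3,
                 dimnames = list(sprintf("S%03d", 1:186),
                                 c("sigA", "sigB", "sigC")))
  w186[1:11, ] <- rep(c(0.1, 0.2, 0.7), each = 11)
  dom_lab <- ifelse(seq_len(186) <= 11, "sigC", "sigA")
  expo186 <- new("ExposureSet", weights = w186, cosine = rep(1, 186),
                 dominant = dom_lab)
  tab <- assignDominant(expo186)$dominance
  expect_equal(tab$n_dominant[tab$signature == "sigC"], 11)
  expect_equal(tab$percent[tab$signature == "sigC"], 5.9)
})

test_that("exact dominance ties resolve to the lexicographically smallest id", {
  expect_equal(HDGCprofiler:::.dominantOf(c(sig5 = 0.5, sig1 = 0.5)), "sig1")
  expect_equal(HDGCprofiler:::.dominantOf(c(s24 = 0.5, s1 = 0.3, s5 = 0.2)),
               "s24")
})

test_that("exposure clustering is seeded, deterministic, and recovers planted groups", {
  set.seed(5)
  w <- rbind(matrix(rep(c(0.9, 0.05, 0.05), each = 10), ncol = 3) +
               matrix(runif(30, 0, 0.02), ncol = 3),
             matrix(rep(c(0.05, 0.05, 0.9), each = 10), ncol = 3) +
               matrix(runif(30, 0, 0.02), ncol = 3))
  w <- w / rowSums(w)
  dimnames(w) <- list(sprintf("S%02d", 1:20), c("sigA", "sigB", "sigC"))
  expo <- new("ExposureSet", weights = w, cosine = rep(1, 20),
              dominant = rep(c("sigA", "sigC"), each = 10))
  cl1 <- clusterExposures(expo, k = 2, seed = 42)
  cl2 <- clusterExposures(expo, k = 2, seed = 42)
  expect_identical(cl1, cl2)
  ari <- mclust::adjustedRandIndex(cl1, rep(1:2, each = 10))
  expect_equal(ari, 1)
  expect_error(clusterExposures(expo, k = 21), "exceeds")
})

test_that("2x2 enrichment counts exclusions and rejects degenerate tables", {
  flagA <- c(rep(TRUE, 3), rep(FALSE, 69), NA, NA)
  flagB <- c(TRUE, TRUE, FALSE, rep(c(TRUE, rep(FALSE, 8)), length.out = 69),
             TRUE, FALSE)
  r <- enrichment2x2(flagA, flagB)
  expect_equal(r$n_excluded, 2)
  expect_equal(sum(r$table), 72)
  expect_equal(r$p, fisherExact(r$table))
  expect_equal(enrichment2x2(rep(c(TRUE, FALSE), 10),
                             rep(c(TRUE, TRUE, FALSE, FALSE), 5))$p,
               1, tolerance = 1e-12)
  expect_error(enrichment2x2(rep(TRUE, 6), rep(c(TRUE, FALSE), 3)),
               "zero margin")
})
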