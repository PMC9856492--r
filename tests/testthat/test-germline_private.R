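test_that("coding SNVs are classified by translating the affected codon", {
  g <- craftedGenome()
  ## codon 3 of the plus-strand gene is TGG at CDS 7-9 = chrT 57-59;
  ## TGG -> TGA by changing its third base
  v <- data.frame(chrom = "chrT", pos = 59, ref = "G", alt = "A")
  out <- classifyConsequence(v, g$gene_model, g$reference)
  expect_equal(out$gene, "GENEP")
  expect_equal(out$consequence, "nonsense")
  ## the oracle agrees: translation gains a stop
  aa_before <- translateCds("GENEP", g$gene_model, g$reference)
  mut <- g$reference
  mut_str <- g$seqstr
  substr(mut_str, 59, 59) <- "A"
  mutref <- Biostrings::DNAStringSet(mut_str); names(mutref) <- "chrT"
  aa_after <- translateCds("GENEP", g$gene_model, mutref)
  expect_false(grepl("\\*", aa_before))
  expect_true(grepl("\\*", aa_after))
})

test_that("minus-strand genes classify through the reverse complement", {
  g <- craftedGenome()
  ## GENEM rank-1 exon is chrT 351-380 holding revcomp(CDS[1:30]); the TGG
  ## codon (CDS 7-9) maps to genomic 372-374 on the minus strand, and its
  ## third base (CDS 9) is genomic 372 with reference C (complement of G)
  expect_equal(substr(g$seqstr, 372, 372), "C")
  out <- classifyConsequence(
    data.frame(chrom = "chrT", pos = 372, ref = "C", alt = "T"),
    g$gene_model, g$reference)
  expect_equal(out$gene, "GENEM")
  expect_equal(out$consequence, "nonsense")
  ## and the identical CDS change gives the identical class on both strands
  plus <- classifyConsequence(
    data.frame(chrom = "chrT", pos = 59, ref = "G", alt = "A"),
    g$gene_model, g$reference)
  expect_equal(out$consequence, plus$consequence)
})

test_that("indel length mod 3 separates frameshift from inframe", {
  g <- craftedGenome()
  b <- function(p, q) substr(g$seqstr, p, q)
  v <- data.frame(chrom = "chrT",
                  pos = c(110, 110),
                  ref = c(b(110, 111), b(110, 113)),
                  alt = c(b(110, 110), b(110, 110)))
  out <- classifyConsequence(v, g$gene_model, g$reference)
  expect_equal(out$consequence, c("frameshift_indel", "inframe_indel"))
})

test_that("intronic positions within 2 bp of a boundary are splice sites", {
  g <- craftedGenome()
  ## GENEP intron 1 spans 81..100
  pos <- c(81, 82, 83, 99, 100, 90)
  ref <- vapply(pos, function(p) substr(g$seqstr, p, p), character(1))
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                character(1))
  out <- classifyConsequence(
    data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt),
    g$gene_model, g$reference)
  expect_equal(out$consequence,
               c("splice_site", "splice_site", "other",
                 "splice_site", "splice_site", "other"))
  ## far from any gene -> other with no gene
  far <- classifyConsequence(
    data.frame(chrom = "chrT", pos = 450,
               ref = substr(g$seqstr, 450, 450),
               alt = setdiff(c("A", "C", "G", "T"),
                             substr(g$seqstr, 450, 450))[1]),
    g$gene_model, g$reference)
  expect_equal(far$gene, "")
  expect_equal(far$consequence, "other")
})

test_that("PTV classes are exactly frameshift, nonsense and splice-site", {
  expect_true(all(isPTV(c("frameshift_indel", "nonsense", "splice_site"))))
  expect_false(any(isPTV(c("missense", "inframe_indel", "synonymous",
                           "other"))))
  expect_error(isPTV("stop_gained"), "unknown consequence")
})

test_that("each criterion gates classifyPrivate with its stated strictness", {
  base <- data.frame(patient_id = "P1", gene = "G1", consequence = "nonsense",
                     zygosity = "het", maf_db1 = 0.004, maf_db2 = 0,
                     occurrence = 1L, mappability = 0.9, unique_locus = TRUE)
  ok <- as.data.frame(privateCalls(classifyPrivate(base)))
  expect_true(ok$is_private)
  tweak <- function(col, val) {
    d <- base; d[[col]] <- val
    as.data.frame(privateCalls(classifyPrivate(d)))
  }
  expect_false(tweak("maf_db1", 0.006)$c3_rare)        # < 0.5% is strict
  expect_true(tweak("maf_db1", 0.0049)$c3_rare)
  expect_false(tweak("mappability", 0.5)$c5_mappable)  # > 0.5 is strict
  expect_true(tweak("mappability", 0.50001)$c5_mappable)
  expect_false(tweak("zygosity", "hom_alt")$c2_het)
  expect_false(tweak("occurrence", 2L)$c4_singleton)
  expect_false(tweak("unique_locus", FALSE)$c6_unique)
  expect_false(tweak("consequence", "synonymous")$c1_consequence)
  ## missense is whitelisted by default but not under the strict PTV list
  expect_true(tweak("consequence", "missense")$is_private)
  strict <- classifyPrivate(transform(base, consequence = "missense"),
                            whitelist = ptvWhitelist())
  expect_false(as.data.frame(privateCalls(strict))$is_private)
  ## OR mode for the two population databases
  d <- transform(base, maf_db1 = 0.01)
  expect_false(as.data.frame(privateCalls(classifyPrivate(d)))$c3_rare)
  expect_true(as.data.frame(privateCalls(
    classifyPrivate(d, maf_mode = "or")))$c3_rare)
  expect_error(classifyPrivate(base[setdiff(names(base), "mappability")]),
               "mappability")
})

test_that("toggling one annotation across its threshold flips exactly one flag", {
  base <- data.frame(patient_id = "P1", gene = "G1", consequence = "nonsense",
                     zygosity = "het", maf_db1 = 0.004, maf_db2 = 0.001,
                     occurrence = 1L, mappability = 0.9, unique_locus = TRUE)
  flags <- function(d) unlist(as.data.frame(privateCalls(
    classifyPrivate(d)))[HDGCprofiler:::.PRIVATE_FLAGS])
  before <- flags(base)
  toggles <- list(consequence = "other", zygosity = "hom_ref",
                  maf_db2 = 0.2, occurrence = 3L, mappability = 0.1,
                  unique_locus = FALSE)
  for (i in seq_along(toggles)) {
    d <- base
    d[[names(toggles)[i]]] <- toggles[[i]]
    after <- flags(d)
    expect_equal(sum(before != after), 1, info = names(toggles)[i])
  }
})

test_that("gene carrier frequencies collapse per patient and round to one decimal", {
  calls <- data.frame(
    patient_id = c("A", "A", "A", "B", "C", "C"),
    gene = c("MUC4", "MUC4", "MUC4", "MUC4", "CDH1", "MUC4"),
    is_private = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  gf <- geneFrequency(calls, 284)
  ## three MUC4 variants in one patient count once
  expect_equal(gf$carrier_count[gf$gene == "MUC4"], 2)
  expect_equal(gf$carrier_count[gf$gene == "CDH1"], 1)
  expect_error(geneFrequency(calls, 0), "> 0")
  ## the reported ratio arithmetic
  expect_equal(carrierPercent(8, 284), 2.8)
  expect_equal(carrierPercent(53, 284), 18.7)
  expect_equal(carrierPercent(1, 284), 0.4)
})
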