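test_that("LOH runs require min_sites consecutive deviant informative sites", {
  sites <- data.frame(pos = seq(100, 1000, by = 100), tumor_vaf = 0.95,
                      depth = 50)
  seg <- callLohSegments(sites)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 99)          # 0-based half-open span of the run
  expect_equal(seg$end, 1000)
  expect_equal(seg$n_het_sites, 10)
  expect_equal(seg$median_deviation, 0.45)
  ## balanced alternating fractions yield nothing
  sites$tumor_vaf <- rep(c(0.48, 0.52), 5)
  expect_equal(nrow(callLohSegments(sites)), 0)
  ## four deviant sites stay below the default run length
  short <- data.frame(pos = 1:4 * 10, tumor_vaf = 0.9, depth = 50)
  expect_equal(nrow(callLohSegments(short)), 0)
  expect_equal(nrow(callLohSegments(short, min_sites = 4)), 1)
  ## shallow sites are skipped without breaking the run
  mix <- data.frame(pos = 1:6 * 10,
                    tumor_vaf = c(0.9, 0.9, 0.5, 0.9, 0.9, 0.9),
                    depth = c(50, 50, 5, 50, 50, 50))
  seg <- callLohSegments(mix)
  expect_equal(seg$n_het_sites, 5)
  ## a balanced deep site does break it
  mix$depth[3] <- 50
  expect_equal(nrow(callLohSegments(mix)), 0)
  expect_error(callLohSegments(data.frame(pos = c(5, 1), tumor_vaf = 0.9,
                                          depth = 50)), "sorted")
})

test_that("double-hit clauses fire independently and tag their evidence", {
  base <- data.frame(patient_id = "P1", gene = "G1", chrom = "chr1",
                     pos = 500L, ref = "A", alt = "T",
                     germline_zygosity = "het",
                     tumor_zygosity = "het", tumor_vaf = 0.5,
                     tumor_depth = 60)
  ev <- function(d, loh = NULL) {
    as.data.frame(doubleHitEvents(callDoubleHits(d, loh)))
  }
  expect_equal(nrow(ev(base)), 0)      # balanced het tumor: no event
  g <- transform(base, tumor_zygosity = "hom_alt", tumor_vaf = 0.6)
  out <- ev(g)
  expect_equal(nrow(out), 1)
  expect_match(out$evidence, "genotype_homozygous")
  v <- transform(base, tumor_vaf = 0.95)
  expect_match(ev(v)$evidence, "vaf_threshold")
  ## vaf clause needs depth
  v$tumor_depth <- 5
  expect_equal(nrow(ev(v)), 0)
  loh <- data.frame(patient_id = "P1", chrom = "chr1", start = 400L,
                    end = 600L)
  l <- transform(base, tumor_vaf = 0.7)
  expect_match(ev(l, loh)$evidence, "loh_overlap")
  ## inside LOH but alt allele lost: not a double hit
  l$tumor_vaf <- 0.2
  expect_equal(nrow(ev(l, loh)), 0)
  ## wrong patient's segment does not count
  loh$patient_id <- "P2"
  expect_equal(nrow(ev(l, loh)), 0)
  expect_error(callDoubleHits(transform(base, germline_zygosity = "hom_alt")),
               "heterozygous")
  expect_warning(callDoubleHits(transform(base, tumor_zygosity = NA,
                                          tumor_vaf = NA)), "skipped")
})

test_that("thresholds are monotone: looser hom_vaf and min_sites behave as expected", {
  set.seed(12)
  n <- 200
  calls <- data.frame(patient_id = "P1", gene = "G", chrom = "chr1",
                      pos = sort(sample(1e5, n)), ref = "A", alt = "T",
                      germline_zygosity = "het",
                      tumor_zygosity = "het",
                      tumor_vaf = runif(n), tumor_depth = 60)
  n_tight <- nrow(doubleHitEvents(callDoubleHits(calls, hom_vaf = 0.95)))
  n_loose <- nrow(doubleHitEvents(callDoubleHits(calls, hom_vaf = 0.8)))
  expect_gte(n_loose, n_tight)
  sites <- data.frame(pos = sort(sample(1e5, n)),
                      tumor_vaf = sample(c(0.5, 0.9), n, TRUE), depth = 60)
  for (ms in c(3, 5, 8))
    expect_gte(nrow(callLohSegments(sites, min_sites = ms)),
               nrow(callLohSegments(sites, min_sites = ms + 1)))
})

test_that("double-hit summaries report the 1-2-event share and both means", {
  ## 66 event-bearing patients, 35 of them with 1-2 events
  counts <- c(rep(1, 20), rep(2, 15), rep(3, 30), 46)
  ev <- do.call(rbind, lapply(seq_along(counts), function(i)
    data.frame(patient_id = sprintf("P%03d", i), gene = "G", chrom = "chr1",
               pos = seq_len(counts[i]) * 10L, ref = "A", alt = "T",
               germline_zygosity = "het", tumor_vaf = 1,
               tumor_depth = 80, evidence = "genotype_homozygous")))
  set <- new("DoubleHitSet", events = S4Vectors::DataFrame(ev))
  all_patients <- sprintf("P%03d", 1:186)
  s <- summarizeDoubleHits(set, all_patients)
  expect_equal(s$overview$n_patients_with_events, 66)
  expect_equal(s$overview$pct_bearing_with_1_2, 53.0)
  expect_equal(s$overview$max_events, 46)
  expect_equal(s$per_patient$n_events[s$per_patient$patient_id == "P066"], 46)
  expect_equal(sum(s$per_patient$n_events == 0), 120)
  expect_equal(s$overview$mean_events_bearing, sum(counts) / 66)
  expect_equal(s$overview$mean_events_all, sum(counts) / 186)
  ## empty set
  empty <- callDoubleHits(data.frame(patient_id = character(),
                                     gene = character(), chrom = character(),
                                     pos = integer(), ref = character(),
                                     alt = character(),
                                     germline_zygosity = character(),
                                     tumor_zygosity = character(),
                                     tumor_vaf = numeric(),
                                     tumor_depth = numeric()))
  s0 <- summarizeDoubleHits(empty, all_patients)
  expect_equal(s0$overview$n_events, 0)
  expect_equal(nrow(s0$per_gene), 0)
})

test_that("the DoubleHitSet class enforces heterozygous germline calls", {
  bad <- S4Vectors::DataFrame(patient_id = "P1", gene = "G", chrom = "c",
                              pos = 1L, ref = "A", alt = "T",
                              germline_zygosity = "hom_alt", tumor_vaf = 1,
                              tumor_depth = 50, evidence = "vaf_threshold")
  expect_error(new("DoubleHitSet", events = bad), "heterozygous")
})

test_that("G scores are frequency times mean amplitude over qualifying overlaps", {
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
                               strand = "+", gene = "G1", exon_rank = 1L)
  segs <- do.call(rbind, lapply(1:10, function(i)
    data.frame(patient_id = sprintf("P%02d", i), chrom = "chr1",
               start = 500L, end = 2500L,
               log2_ratio = if (i <= 5) 0.8 else 0.1)))
  gs <- geneGScore(segs, gm, n_patients = 10)
  expect_equal(gs$amp_freq, 0.5)
  expect_equal(gs$g_amp, 0.5 * 0.8)
  expect_equal(gs$g_del, 0)
  ## deletions only
  segs$log2_ratio <- -0.6
  gs <- geneGScore(segs, gm, n_patients = 10)
  expect_equal(gs$g_amp, 0)
  expect_equal(gs$g_del, 1 * 0.6)
  ## no overlap at all -> zeros
  far <- transform(segs, start = 5000L, end = 6000L)
  gs <- geneGScore(far, gm, n_patients = 10)
  expect_equal(unlist(gs[, c("amp_freq", "del_freq", "g_amp", "g_del")]),
               c(amp_freq = 0, del_freq = 0, g_amp = 0, g_del = 0))
})
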