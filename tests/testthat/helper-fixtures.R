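# Fixtures built in code: a crafted two-gene contig with a hand-written CDS
# (so codon-level expectations are known) and lazily cached synthetic
# bundles shared across test files.

# 30 codons, no stop codons; codon 3 is TGG (one substitution from TGA).
CRAFTED_CDS <- paste0(
  "ATGGCTTGGAAACTTGAGGATCCGTACGTC",
  "ATCAACTGCCGAGGATTTAGCGTGCATATG",
  "GCCAAGGATCTGGAATTCGGTACCAGTGCA")

# Layout on contig "chrT" (1-based):
#   plus-strand gene GENEP: exons 51-80, 101-130, 151-180 (ranks 1..3)
#   minus-strand gene GENEM: exons 251-280, 301-330, 351-380 (ranks 3..1)
craftedGenome <- function() {
  set.seed(424242)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  cds <- CRAFTED_CDS
  revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seqstr <- paste0(
    rnd(50),
    substr(cds, 1, 30), rnd(20), substr(cds, 31, 60), rnd(20),
    substr(cds, 61, 90),
    rnd(70),
    revcomp(substr(cds, 61, 90)), rnd(20), revcomp(substr(cds, 31, 60)),
    rnd(20), revcomp(substr(cds, 1, 30)),
    rnd(120))
  reference <- Biostrings::DNAStringSet(seqstr)
  names(reference) <- "chrT"
  gene_model <- GenomicRanges::GRanges(
    "chrT",
    IRanges::IRanges(c(51, 101, 151, 251, 301, 351),
                     c(80, 130, 180, 280, 330, 380)),
    strand = c("+", "+", "+", "-", "-", "-"),
    gene = c("GENEP", "GENEP", "GENEP", "GENEM", "GENEM", "GENEM"),
    exon_rank = c(1L, 2L, 3L, 3L, 2L, 1L))
  list(reference = reference, gene_model = gene_model, seqstr = seqstr)
}

# A contig with a homopolymer run for indel-normalization cases.
slipperyContig <- function() {
  set.seed(99)
  pre <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  seqstr <- paste0(pre, "CTAAAAG",
                   paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                         collapse = ""))
  ref <- Biostrings::DNAStringSet(seqstr)
  names(ref) <- "chrS"
  list(reference = ref, seqstr = seqstr)
}

.bundle_cache <- new.env(parent = emptyenv())

cachedBundle <- function(name, config) {
  if (is.null(.bundle_cache[[name]])) {
    dir <- file.path(tempdir(), paste0("hdgc_bundle_", name))
    .bundle_cache[[name]] <- simulateCohort(config, dir)
  }
  .bundle_cache[[name]]
}

cachedPipeline <- function(name, bundle, config = pipelineConfig()) {
  key <- paste0("run_", name)
  if (is.null(.bundle_cache[[key]])) {
    outdir <- file.path(tempdir(), paste0("hdgc_out_", name))
    .bundle_cache[[key]] <- suppressMessages(
      runPipeline(bundleDir(bundle), outdir, config))
    attr(.bundle_cache[[key]], "outdir") <- outdir
  }
  .bundle_cache[[key]]
}

smallConfig <- function(seed = 5L, ...) {
  simulationConfig(seed = seed, n_patients = 10L, n_genes = 16L,
                   n_common = 120L, n_somatic = 80L, double_hit_count = 5L,
                   decoys_per_criterion = 1L, ...)
}

# the cohort-scale study bundles used by the recovery checks
noiselessBundle <- function()
  cachedBundle("noiseless50", simulationConfig(seed = 101L, read_noise = FALSE))
noisyBundle <- function()
  cachedBundle("noisy50", simulationConfig(seed = 202L, read_noise = TRUE,
                                           mean_depth = 80L))

plantedKey <- function(d) paste(d$patient_id, d$chrom, d$pos, d$ref, d$alt)

# Copy a bundle into a fresh directory (so destructive edits never touch the
# shared cached bundle).
copyBundle <- function(bundle, name) {
  stage <- file.path(tempdir(), paste0(name, "_stage"))
  dest <- file.path(tempdir(), name)
  unlink(stage, recursive = TRUE)
  unlink(dest, recursive = TRUE)
  dir.create(stage)
  file.copy(bundleDir(bundle), stage, recursive = TRUE)
  file.rename(file.path(stage, basename(bundleDir(bundle))), dest)
  unlink(stage, recursive = TRUE)
  dest
}
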