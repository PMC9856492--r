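## Synthetic paired tumor-normal exome cohorts with planted ground truth.
##
## The generator emits a miniature but complete input bundle: a reference,
## a multi-exon gene model, a population frequency table, mappability and
## locus-uniqueness tracks, per-patient germline+tumor VCFs, a clinical
## manifest with family history and survival, a toy signature matrix, and
## copy-number segments -- together with truth tables for every planted
## feature, so each pipeline stage can be scored against known answers.

#' Simulation configuration
#'
#' Defaults emulate the structure of a clinically ascertained HDGC exome
#' cohort: ~8 private germline variants per patient with one flagship gene
#' near 19% carrier frequency and a CDH1-like gene at 2.8%, decoy variants
#' violating exactly one private-variant criterion each, a qualifying-
#' condition mix of 8/2.5/89.4/0 percent, EBV positivity near 2.8%, LOH
#' segments converting planted heterozygotes to homozygous in the tumor,
#' and somatic SNVs drawn from per-sample Dirichlet mixtures of three toy
#' signatures (EBV-positive tumors lean towards the third signature so
#' subgroup enrichment has signal).
#'
#' @param seed integer; fixes all randomness.
#' @param n_patients cohort size.
#' @param n_contigs,contig_length genome shape.
#' @param n_genes number of protein-coding genes (3 CDS exons of 90 bp each).
#' @param private_rate expected private variants per patient per gene;
#'   either a single value or a vector of length `n_genes`. The default
#'   vector gives carrier fractions (1 - exp(-rate)) of ~18.7% for gene 1,
#'   ~10% for genes 2-7, 2.8% for gene 8 and ~18% elsewhere.
#' @param fraction_ptv fraction of planted private variants that are PTVs
#'   (split evenly across nonsense, frameshift, splice-site); the remainder
#'   are missense.
#' @param decoys_per_criterion planted decoys per private-variant criterion,
#'   each violating exactly that criterion.
#' @param double_hit_count planted double-hit events cohort-wide.
#' @param loh_window width (bp) of planted LOH windows.
#' @param loh_extra_per_tumor background LOH windows per tumor containing no
#'   double hit.
#' @param n_common common polymorphic sites (population frequency 0.1-0.5).
#' @param common_het_prob,common_hom_prob per-patient genotype probabilities
#'   at common sites.
#' @param n_somatic expected somatic SNVs per tumor.
#' @param signature_alpha,signature_alpha_ebv Dirichlet parameters of the
#'   per-sample signature mixture (EBV-negative/unknown vs EBV-positive).
#' @param mean_depth sequencing depth; with `read_noise` depths are Poisson
#'   and allele counts binomial, otherwise depths and fractions are exact.
#' @param read_noise logical; FALSE gives a noiseless bundle.
#' @param somatic_vaf tumor allele fraction of somatic SNVs.
#' @param condition_mix probabilities of HDGC conditions 1-4 per patient
#'   (any remainder yields a non-qualifying patient).
#' @param ebv_mix probabilities of positive/negative/unknown EBV status.
#' @param surv_5yr target 5-year survival used for the exponential event
#'   model; censoring is uniform administrative follow-up on (3, 186)
#'   months.
#' @return a config list for [simulateCohort()].
#' @export
simulationConfig <- function(seed = 1L,
                             n_patients = 50L,
                             n_contigs = 2L,
                             contig_length = 60000L,
                             n_genes = 40L,
                             private_rate = NULL,
                             fraction_ptv = 0.6,
                             decoys_per_criterion = 2L,
                             double_hit_count = 12L,
                             loh_window = 3000L,
                             loh_extra_per_tumor = 1L,
                             n_common = 300L,
                             common_het_prob = 0.55,
                             common_hom_prob = 0.05,
                             n_somatic = 300L,
                             signature_alpha = c(1, 1, 1),
                             signature_alpha_ebv = c(0.5, 0.5, 5),
                             mean_depth = 80L,
                             read_noise = TRUE,
                             somatic_vaf = 0.4,
                             condition_mix = c(0.08, 0.025, 0.894, 0),
                             ebv_mix = c(positive = 8, negative = 209,
                                         unknown = 63) / 280,
                             surv_5yr = 0.614) {
  if (is.null(private_rate)) {
    private_rate <- rep(0.2, n_genes)
    private_rate[1L] <- 0.207                      # flagship, ~18.7% carriers
    if (n_genes >= 7L) private_rate[2:7] <- 0.105  # ~10% tier
    if (n_genes >= 8L) private_rate[8L] <- 0.0284  # CDH1-like, ~2.8%
  }
  if (length(private_rate) == 1L) private_rate <- rep(private_rate, n_genes)
  stopifnot(length(private_rate) == n_genes,
            all(private_rate >= 0), fraction_ptv >= 0, fraction_ptv <= 1,
            all(condition_mix >= 0), sum(condition_mix) <= 1 + 1e-9,
            somatic_vaf > 0, somatic_vaf <= 1)
  as.list(environment())
}

.BASES4 <- c("A", "C", "G", "T")

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Three toy mutational signatures
#'
#' Deterministic 96-category signatures with low pairwise cosine similarity
#' (< 0.2), each concentrated in a different substitution class with smooth
#' context structure: sigA in C>T (deamination-like), sigB in C>A, sigC in
#' T>C. They exist so signature refitting is testable without any external
#' signature download.
#'
#' @return a [SignatureSet-class] with signatures `sigA`, `sigB`, `sigC`.
#' @export
toySignatures <- function() {
  peak <- function(class_idx, center, width, floor_w = 0.002) {
    w <- rep(floor_w, 96)
    block <- (class_idx - 1L) * 16L + 1:16
    w[block] <- w[block] + exp(-((1:16 - center) / width)^2)
    w / sum(w)
  }
  m <- cbind(sigA = peak(3L, 6, 3),    # C>T
             sigB = peak(1L, 11, 4),   # C>A
             sigC = peak(5L, 4, 5))    # T>C
  SignatureSet(m)
}

## enumerate SNV planting candidates for one gene: for every CDS position
## and alternate base, the genomic representation and consequence class
.snvCandidates <- function(gi) {
  len <- nchar(gi$cds_seq)
  widths <- gi$exon_end - gi$exon_start + 1L
  code <- Biostrings::GENETIC_CODE
  out <- vector("list", len * 3L)
  n <- 0L
  for (cpos in seq_len(len)) {
    ei <- findInterval(cpos - 1L, gi$cum_before)  # exon index in rank order
    off <- cpos - gi$cum_before[ei]
    gpos <- if (gi$strand == "+") gi$exon_start[ei] + off - 1L
            else gi$exon_end[ei] - off + 1L
    cb <- substr(gi$cds_seq, cpos, cpos)
    ci <- (cpos - 1L) %/% 3L
    codon <- substr(gi$cds_seq, 3L * ci + 1L, 3L * ci + 3L)
    coff <- cpos - 3L * ci
    for (ab in setdiff(.BASES4, cb)) {
      alt_codon <- codon
      substr(alt_codon, coff, coff) <- ab
      ref_aa <- code[[codon]]; alt_aa <- code[[alt_codon]]
      type <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
              else if (alt_aa == ref_aa) "synonymous"
              else if (ref_aa == "*") "other"
              else "missense"
      if (type == "other") next
      gref <- if (gi$strand == "+") cb else .COMPLEMENT[[cb]]
      galt <- if (gi$strand == "+") ab else .COMPLEMENT[[ab]]
      n <- n + 1L
      out[[n]] <- data.frame(pos = gpos, ref = gref, alt = galt,
                             type = type, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(n)])
}

.spliceCandidates <- function(gi) {
  if (is.null(gi$splice)) return(NULL)
  pos <- unlist(lapply(seq_len(nrow(gi$splice)), function(i)
    gi$splice[i, 1L]:gi$splice[i, 2L]))
  data.frame(pos = pos, type = "splice_site", stringsAsFactors = FALSE)
}

.frameshiftCandidates <- function(gi) {
  pos <- unlist(lapply(seq_along(gi$exon_start), function(i) {
    s <- gi$exon_start[i] + 5L; e <- gi$exon_end[i] - 5L
    if (s > e) integer() else s:e
  }))
  data.frame(pos = pos, type = "frameshift_indel", stringsAsFactors = FALSE)
}

## positions of each trinucleotide in the reference (both strands handled at
## draw time); returns list tri -> integer positions, per contig
.triIndex <- function(reference) {
  lapply(as.list(as.character(reference)), function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    tri <- paste0(ch[1:(L - 2L)], ch[2:(L - 1L)], ch[3:L])
    split(2:(L - 1L), tri)
  })
}

.revcompTri <- function(tri) {
  paste(rev(.COMPLEMENT[strsplit(tri, "")[[1]]]), collapse = "")
}

#' Generate a synthetic cohort bundle
#'
#' Writes the full input bundle plus truth tables under `outdir` and returns
#' a [SyntheticBundle-class]. Deterministic given `config$seed`: the same
#' config always yields byte-identical files.
#'
#' @param config from [simulationConfig()].
#' @param outdir output directory (created; existing files overwritten).
#' @return a [SyntheticBundle-class].
#' @export
simulateCohort <- function(config, outdir) {
  cf <- config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  set.seed(cf$seed)

  ## ---- reference and gene model -------------------------------------------
  contigs <- paste0("chr", seq_len(cf$n_contigs))
  ref_seq <- Biostrings::DNAStringSet(vapply(contigs, function(ch)
    paste(sample(.BASES4, cf$contig_length, replace = TRUE), collapse = ""),
    character(1)))
  names(ref_seq) <- contigs

  exon_len <- 90L; n_exons <- 3L; intron_len <- 30L; gene_gap <- 800L
  gene_len <- n_exons * exon_len + (n_exons - 1L) * intron_len
  per_contig <- ceiling(cf$n_genes / cf$n_contigs)
  if (500L + per_contig * (gene_len + gene_gap) > cf$contig_length)
    stop("contig too short for the requested number of genes")
  gm_rows <- list()
  for (gidx in seq_len(cf$n_genes)) {
    ci <- ((gidx - 1L) %% cf$n_contigs) + 1L
    slot <- (gidx - 1L) %/% cf$n_contigs
    gstart <- 500L + slot * (gene_len + gene_gap)
    strand <- if (gidx %% 2L == 0L) "-" else "+"
    for (e in seq_len(n_exons)) {
      es <- gstart + (e - 1L) * (exon_len + intron_len)
      rank <- if (strand == "+") e else n_exons - e + 1L
      gm_rows[[length(gm_rows) + 1L]] <- data.frame(
        chrom = contigs[ci], start = es, end = es + exon_len,
        gene = sprintf("GENE%02d", gidx), exon_rank = rank, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  gene_model_df <- do.call(rbind, gm_rows)
  gm_path <- file.path(outdir, "gene_model.bed")
  utils::write.table(gene_model_df, gm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fa_path <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(ref_seq, fa_path)
  gene_model <- readGeneModel(gm_path)
  gidx_list <- .geneIndex(gene_model, ref_seq)
  genes <- names(gidx_list)

  ## ---- planting machinery -------------------------------------------------
  used <- lapply(contigs, function(x) integer())
  names(used) <- contigs
  is_free <- function(ch, pos, pad = 4L) {
    !length(used[[ch]]) || all(abs(used[[ch]] - pos) > pad)
  }
  reserve <- function(ch, pos) used[[ch]] <<- c(used[[ch]], pos)

  snv_cand <- lapply(gidx_list, .snvCandidates)
  spl_cand <- lapply(gidx_list, .spliceCandidates)
  fs_cand <- lapply(gidx_list, .frameshiftCandidates)

  ## draw one planting candidate of the requested type in a gene, returning
  ## the normalized variant representation, or NULL if the gene is exhausted
  draw_variant <- function(gene, type) {
    gi <- gidx_list[[gene]]
    ch <- gi$chrom
    for (try in 1:50) {
      if (type %in% c("nonsense", "missense", "synonymous")) {
        cand <- snv_cand[[gene]]
        cand <- cand[cand$type == type, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        row <- cand[sample.int(nrow(cand), 1L), ]
        if (!is_free(ch, row$pos)) next
        reserve(ch, row$pos)
        return(data.frame(chrom = ch, pos = row$pos, ref = row$ref,
                          alt = row$alt, consequence = type,
                          stringsAsFactors = FALSE))
      } else if (type == "splice_site") {
        cand <- spl_cand[[gene]]
        if (is.null(cand) || !nrow(cand)) return(NULL)
        p <- cand$pos[sample.int(nrow(cand), 1L)]
        if (!is_free(ch, p)) next
        rb <- .refSlice(ref_seq, ch, p, p)
        ab <- sample(setdiff(.BASES4, rb), 1L)
        reserve(ch, p)
        return(data.frame(chrom = ch, pos = p, ref = rb, alt = ab,
                          consequence = "splice_site",
                          stringsAsFactors = FALSE))
      } else if (type == "frameshift_indel") {
        cand <- fs_cand[[gene]]
        p <- cand$pos[sample.int(nrow(cand), 1L)]
        if (!is_free(ch, p, pad = 6L)) next
        r2 <- .refSlice(ref_seq, ch, p - 1L, p)
        nk <- normalizeVariant(ch, p - 1L, r2, substr(r2, 1L, 1L), ref_seq)
        ## keep the normalized deletion strictly inside its exon
        ei <- which(gi$exon_start <= p & gi$exon_end >= p)[1L]
        if (nk$pos <= gi$exon_start[ei] || !is_free(ch, nk$pos, pad = 6L)) next
        reserve(ch, p); reserve(ch, nk$pos)
        return(data.frame(chrom = ch, pos = nk$pos, ref = nk$ref,
                          alt = nk$alt, consequence = "frameshift_indel",
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  }

  patients <- sprintf("P%03d", seq_len(cf$n_patients))

  ## ---- private variants ---------------------------------------------------
  ptv_types <- c("nonsense", "frameshift_indel", "splice_site")
  truth_private <- list()
  for (pi in seq_along(patients)) {
    for (g in seq_along(genes)) {
      k <- stats::rpois(1L, cf$private_rate[g])
      for (j in seq_len(k)) {
        type <- if (stats::runif(1) < cf$fraction_ptv)
          sample(ptv_types, 1L) else "missense"
        v <- draw_variant(genes[g], type)
        if (is.null(v)) next
        truth_private[[length(truth_private) + 1L]] <- cbind(
          data.frame(patient_id = patients[pi], gene = genes[g],
                     stringsAsFactors = FALSE),
          v,
          data.frame(role = "private", zygosity = "het",
                     c1_consequence = TRUE, c2_het = TRUE, c3_rare = TRUE,
                     c4_singleton = TRUE, c5_mappable = TRUE,
                     c6_unique = TRUE, is_private = TRUE,
                     stringsAsFactors = FALSE))
      }
    }
  }

  ## ---- decoys: each violates exactly one criterion ------------------------
  decoy_rows <- list()
  freq_extra <- list()
  mapp_holes <- list(); uniq_holes <- list()
  flags_true <- c(c1_consequence = TRUE, c2_het = TRUE, c3_rare = TRUE,
                  c4_singleton = TRUE, c5_mappable = TRUE, c6_unique = TRUE)
  add_decoy <- function(crit) {
    g <- sample(genes, 1L)
    type <- if (crit == 1L) "synonymous" else "missense"
    v <- draw_variant(g, type)
    if (is.null(v)) return(NULL)
    carriers <- sample(patients, if (crit == 4L) 2L else 1L)
    zyg <- if (crit == 2L) "hom_alt" else "het"
    fl <- flags_true
    fl[crit] <- FALSE
    if (crit == 3L)
      freq_extra[[length(freq_extra) + 1L]] <<- data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        freq1 = 0.006, freq2 = 0, stringsAsFactors = FALSE)
    if (crit == 5L)
      mapp_holes[[length(mapp_holes) + 1L]] <<- data.frame(
        chrom = v$chrom, start = v$pos - 1L, end = v$pos + nchar(v$ref) - 1L,
        value = 0.4, stringsAsFactors = FALSE)
    if (crit == 6L)
      uniq_holes[[length(uniq_holes) + 1L]] <<- data.frame(
        chrom = v$chrom, start = v$pos - 1L, end = v$pos + nchar(v$ref) - 1L,
        value = 0, stringsAsFactors = FALSE)
    lapply(carriers, function(p) cbind(
      data.frame(patient_id = p, gene = g, stringsAsFactors = FALSE),
      v,
      data.frame(role = sprintf("decoy_c%d", crit), zygosity = zyg,
                 as.list(fl), is_private = FALSE, stringsAsFactors = FALSE)))
  }
  for (crit in 1:6)
    for (r in seq_len(cf$decoys_per_criterion)) {
      d <- add_decoy(crit)
      if (!is.null(d)) decoy_rows <- c(decoy_rows, d)
    }

  planted <- do.call(rbind, c(truth_private, decoy_rows))
  rownames(planted) <- NULL

  ## ---- common polymorphic sites -------------------------------------------
  common <- list()
  for (j in seq_len(cf$n_common)) {
    for (try in 1:50) {
      ch <- sample(contigs, 1L)
      p <- sample(100:(cf$contig_length - 100L), 1L)
      if (!is_free(ch, p)) next
      rb <- .refSlice(ref_seq, ch, p, p)
      ab <- sample(setdiff(.BASES4, rb), 1L)
      reserve(ch, p)
      common[[length(common) + 1L]] <- data.frame(
        chrom = ch, pos = p, ref = rb, alt = ab,
        freq1 = round(stats::runif(1, 0.1, 0.5), 4),
        freq2 = round(stats::runif(1, 0.1, 0.5), 4),
        stringsAsFactors = FALSE)
      break
    }
  }
  common <- do.call(rbind, common)
  common <- common[order(common$chrom, common$pos), , drop = FALSE]

  freq_df <- rbind(common,
                   if (length(freq_extra)) do.call(rbind, freq_extra))
  freq_path <- file.path(outdir, "frequency.tsv")
  .writeTsv(freq_df[order(freq_df$chrom, freq_df$pos), ], freq_path)

  mapp_df <- rbind(data.frame(chrom = contigs[1L], start = 0L, end = 1L,
                              value = 1, stringsAsFactors = FALSE),
                   if (length(mapp_holes)) do.call(rbind, mapp_holes))
  uniq_df <- rbind(data.frame(chrom = contigs[1L], start = 0L, end = 1L,
                              value = 1, stringsAsFactors = FALSE),
                   if (length(uniq_holes)) do.call(rbind, uniq_holes))
  mapp_path <- file.path(outdir, "mappability.bed")
  uniq_path <- file.path(outdir, "uniqueness.bed")
  utils::write.table(mapp_df, mapp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(uniq_df, uniq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ## ---- clinical manifest, family history, survival ------------------------
  cond_levels <- c("1", "2", "3", "4", "none")
  cond_prob <- c(cf$condition_mix, max(0, 1 - sum(cf$condition_mix)))
  planted_condition <- sample(cond_levels, cf$n_patients, replace = TRUE,
                              prob = cond_prob)
  fam_rows <- list()
  clin_rows <- list()
  lambda <- -log(cf$surv_5yr) / 60
  for (pi in seq_along(patients)) {
    pc <- planted_condition[pi]
    fam <- NULL
    if (pc == "3") {
      age <- sample(20:39, 1L); hist <- "diffuse"
    } else if (pc == "1") {
      age <- sample(41:70, 1L); hist <- "diffuse"
      fam <- data.frame(patient_id = patients[pi], degree = c(1L, 2L),
                        diagnosis = c("GC", "diffuse_GC"),
                        age_at_dx = c(sample(50:70, 1L), sample(35:49, 1L)),
                        confirmed = c(FALSE, TRUE), stringsAsFactors = FALSE)
    } else if (pc == "2") {
      age <- sample(41:70, 1L); hist <- "diffuse"
      fam <- data.frame(patient_id = patients[pi], degree = c(1L, 1L, 2L),
                        diagnosis = "diffuse_GC",
                        age_at_dx = sample(50:75, 3L, replace = TRUE),
                        confirmed = TRUE, stringsAsFactors = FALSE)
    } else if (pc == "4") {
      age <- sample(41:49, 1L); hist <- "diffuse"
      fam <- data.frame(patient_id = patients[pi], degree = 1L,
                        diagnosis = "lobular_breast",
                        age_at_dx = sample(50:70, 1L),
                        confirmed = TRUE, stringsAsFactors = FALSE)
    } else {
      age <- sample(45:70, 1L); hist <- "other"
    }
    if (!is.null(fam)) fam_rows[[length(fam_rows) + 1L]] <- fam
    ev_t <- stats::rexp(1, lambda)
    cens <- stats::runif(1, 3, 186)
    clin_rows[[length(clin_rows) + 1L]] <- data.frame(
      patient_id = patients[pi], age_at_dx = age, histology = hist,
      sex = sample(c("female", "male"), 1L, prob = c(0.567, 0.433)),
      personal_lobular_breast = pc == "4",
      t_category = sample(c("T1", "T2", "T3", "T4", "TX"), 1L,
                          prob = c(0.11, 0.12, 0.33, 0.33, 0.11)),
      n_category = sample(c("N0", "N1", "N2", "N3", "NX"), 1L,
                          prob = c(0.16, 0.16, 0.28, 0.29, 0.11)),
      m_category = sample(c("M0", "M1"), 1L, prob = c(0.708, 0.292)),
      stage = sample(c("I", "II", "III", "IV"), 1L,
                     prob = c(0.16, 0.17, 0.34, 0.33)),
      ebv_status = sample(names(cf$ebv_mix), 1L, prob = cf$ebv_mix),
      survival_months = round(min(ev_t, cens), 1),
      event = ev_t <= cens,
      planted_condition = pc,
      stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, clin_rows)
  family <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(patient_id = character(), degree = integer(),
               diagnosis = character(), age_at_dx = numeric(),
               confirmed = logical())
  clin_path <- file.path(outdir, "clinical.tsv")
  fam_path <- file.path(outdir, "family.tsv")
  .writeTsv(clinical, clin_path)
  .writeTsv(family, fam_path)

  ## ---- common genotypes per patient ---------------------------------------
  ## status 0 = absent, 1 = het, 2 = hom_alt
  common_gt <- matrix(sample(0:2, cf$n_patients * nrow(common), replace = TRUE,
                             prob = c(1 - cf$common_het_prob - cf$common_hom_prob,
                                      cf$common_het_prob, cf$common_hom_prob)),
                      nrow = cf$n_patients,
                      dimnames = list(patients, NULL))

  ## ---- double hits and LOH windows ----------------------------------------
  priv <- planted[planted$role == "private", , drop = FALSE]
  if (cf$double_hit_count > nrow(priv))
    stop("double_hit_count exceeds the number of planted private variants")
  dh_idx <- if (cf$double_hit_count > 0L)
    sample(nrow(priv), cf$double_hit_count) else integer()
  truth_dh <- priv[dh_idx, c("patient_id", "gene", "chrom", "pos", "ref",
                             "alt"), drop = FALSE]
  rownames(truth_dh) <- NULL
  dh_key <- paste(truth_dh$patient_id,
                  .keyString(truth_dh$chrom, truth_dh$pos, truth_dh$ref,
                             truth_dh$alt))

  half <- cf$loh_window %/% 2L
  windows <- list()   # per patient: data.frame(chrom, start, end) 1-based inclusive
  for (pi in seq_along(patients)) {
    p <- patients[pi]
    dhp <- truth_dh[truth_dh$patient_id == p, , drop = FALSE]
    win <- NULL
    if (nrow(dhp)) {
      for (ch in unique(dhp$chrom)) {
        pos <- sort(dhp$pos[dhp$chrom == ch])
        grp <- cumsum(c(1L, diff(pos) > (cf$loh_window + 3000L)))
        for (g in unique(grp)) {
          pg <- pos[grp == g]
          win <- rbind(win, data.frame(
            chrom = ch,
            start = max(1L, min(pg) - half),
            end = min(cf$contig_length, max(pg) + half),
            stringsAsFactors = FALSE))
        }
      }
    }
    for (j in seq_len(cf$loh_extra_per_tumor)) {
      for (try in 1:30) {
        ch <- sample(contigs, 1L)
        s <- sample(1000:(cf$contig_length - cf$loh_window - 1000L), 1L)
        e <- s + cf$loh_window
        clash <- !is.null(win) && any(win$chrom == ch &
                                        win$start < e + 3000L &
                                        win$end > s - 3000L)
        if (!clash) {
          win <- rbind(win, data.frame(chrom = ch, start = s, end = e,
                                       stringsAsFactors = FALSE))
          break
        }
      }
    }
    windows[[p]] <- win
  }

  ## ---- somatic SNVs from signature mixtures --------------------------------
  sigs <- toySignatures()
  sig_path <- file.path(outdir, "signatures.tsv")
  writeSignatureMatrix(sigs, sig_path)
  S <- signatureProbs(sigs)
  tri_idx <- .triIndex(ref_seq)
  cats <- sbs96Categories()
  ## category -> (pyrimidine triple, alt base) decomposition
  cat_parts <- do.call(rbind, lapply(cats, function(lbl) {
    data.frame(f = substr(lbl, 1L, 1L), r = substr(lbl, 3L, 3L),
               a = substr(lbl, 5L, 5L), t = substr(lbl, 7L, 7L),
               stringsAsFactors = FALSE)
  }))

  truth_expo <- list()
  somatic_rows <- list()
  for (pi in seq_along(patients)) {
    p <- patients[pi]
    ebv <- clinical$ebv_status[pi]
    alpha <- if (ebv == "positive") cf$signature_alpha_ebv else cf$signature_alpha
    w <- .rdirichlet(alpha)
    n_mut <- stats::rpois(1L, cf$n_somatic)
    probs <- as.numeric(S %*% w)
    cat_draw <- sample.int(96L, n_mut, replace = TRUE, prob = probs)
    taken <- lapply(contigs, function(x) integer()); names(taken) <- contigs
    germ_pos <- planted$pos[planted$patient_id == p]
    germ_chrom <- planted$chrom[planted$patient_id == p]
    rows <- list()
    for (cidx in cat_draw) {
      cp <- cat_parts[cidx, ]
      pyr_tri <- paste0(cp$f, cp$r, cp$t)
      rev_tri <- .revcompTri(pyr_tri)
      for (try in 1:30) {
        ch <- sample(contigs, 1L)
        fwd <- tri_idx[[ch]][[pyr_tri]]
        rev <- tri_idx[[ch]][[rev_tri]]
        pool_n <- length(fwd) + length(rev)
        if (!pool_n) next
        k <- sample.int(pool_n, 1L)
        if (k <= length(fwd)) { pos <- fwd[k]; alt <- cp$a; rb <- cp$r }
        else { pos <- rev[k - length(fwd)]
               alt <- .COMPLEMENT[[cp$a]]; rb <- .COMPLEMENT[[cp$r]] }
        if (pos %in% taken[[ch]]) next
        if (any(germ_chrom == ch & abs(germ_pos - pos) < 3L)) next
        if (pos %in% common$pos[common$chrom == ch]) next
        taken[[ch]] <- c(taken[[ch]], pos)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = pos, ref = rb, alt = alt,
          stringsAsFactors = FALSE)
        break
      }
    }
    som <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character())
    somatic_rows[[p]] <- som
    truth_expo[[pi]] <- data.frame(sample_id = p, ebv_status = ebv,
                                   sigA = w[1], sigB = w[2], sigC = w[3],
                                   n_somatic = nrow(som),
                                   stringsAsFactors = FALSE)
  }
  truth_expo <- do.call(rbind, truth_expo)

  ## ---- per-patient VCFs ----------------------------------------------------
  depth_of <- function(n) {
    if (cf$read_noise) pmax(10L, stats::rpois(n, cf$mean_depth))
    else rep(as.integer(cf$mean_depth), n)
  }
  alt_of <- function(depth, vaf_target) {
    if (cf$read_noise) stats::rbinom(length(depth), depth, vaf_target)
    else as.integer(round(depth * vaf_target))
  }
  in_window <- function(win, ch, pos) {
    !is.null(win) && any(win$chrom == ch & win$start <= pos & win$end >= pos)
  }

  truth_loh <- list()
  contig_lengths <- stats::setNames(rep(cf$contig_length, cf$n_contigs),
                                    contigs)
  for (pi in seq_along(patients)) {
    p <- patients[pi]
    mine <- planted[planted$patient_id == p, , drop = FALSE]
    cg <- common_gt[p, ]
    carried <- which(cg > 0L)
    g_rows <- rbind(
      if (nrow(mine)) data.frame(chrom = mine$chrom, pos = mine$pos,
                                 ref = mine$ref, alt = mine$alt,
                                 zyg = ifelse(mine$zygosity == "het", 1L, 2L),
                                 role = mine$role,
                                 stringsAsFactors = FALSE),
      if (length(carried)) data.frame(chrom = common$chrom[carried],
                                      pos = common$pos[carried],
                                      ref = common$ref[carried],
                                      alt = common$alt[carried],
                                      zyg = cg[carried], role = "common",
                                      stringsAsFactors = FALSE))
    g_rows <- g_rows[order(g_rows$chrom, g_rows$pos), , drop = FALSE]
    n <- nrow(g_rows)
    gdepth <- depth_of(n)
    gvaf_target <- ifelse(g_rows$zyg == 1L, 0.5, 1)
    galt <- alt_of(gdepth, gvaf_target)
    galt[g_rows$zyg == 2L] <- gdepth[g_rows$zyg == 2L]  # hom stays hom
    ggt <- ifelse(g_rows$zyg == 1L, "0/1", "1/1")

    ## tumor state per germline row; adjacent LOH windows with no germline
    ## het site between them first merge into one (the allele-fraction
    ## caller cannot distinguish them, so neither may the truth)
    win <- windows[[p]]
    if (!is.null(win) && nrow(win) > 1L) {
      het_by_chrom <- split(g_rows$pos[g_rows$zyg == 1L],
                            g_rows$chrom[g_rows$zyg == 1L])
      win <- win[order(win$chrom, win$start), , drop = FALSE]
      merged <- win[1L, , drop = FALSE]
      for (wi in 2:nrow(win)) {
        last <- nrow(merged)
        hp <- het_by_chrom[[win$chrom[wi]]]
        sep <- !is.null(hp) && any(hp > merged$end[last] &
                                     hp < win$start[wi])
        if (win$chrom[wi] == merged$chrom[last] && !sep)
          merged$end[last] <- max(merged$end[last], win$end[wi])
        else merged <- rbind(merged, win[wi, , drop = FALSE])
      }
      win <- merged
    }
    key <- paste(p, .keyString(g_rows$chrom, g_rows$pos, g_rows$ref,
                               g_rows$alt))
    is_dh <- key %in% dh_key
    inw <- vapply(seq_len(n), function(i)
      in_window(win, g_rows$chrom[i], g_rows$pos[i]), logical(1))
    t_target <- gvaf_target
    t_state <- ifelse(g_rows$zyg == 2L, "hom", "het")
    for (i in seq_len(n)) {
      if (g_rows$zyg[i] != 1L) next
      if (is_dh[i]) { t_target[i] <- 1; t_state[i] <- "dh" }
      else if (inw[i]) {
        if (g_rows$role[i] == "common") {
          keep <- stats::runif(1) < 0.5
          t_target[i] <- if (keep) 1 else 0
        } else t_target[i] <- 0            # planted non-DH variants lose the alt
        t_state[i] <- "loh"
      }
    }
    if (cf$read_noise) {
      t_target[t_state %in% c("dh", "loh") & t_target == 1] <- 0.95
      t_target[t_state %in% c("dh", "loh") & t_target == 0] <- 0.05
    }
    tdepth <- depth_of(n)
    talt <- alt_of(tdepth, t_target)
    tgt <- ifelse(t_target >= 0.75, "1/1", ifelse(t_target <= 0.25, "0/0",
                                                  "0/1"))
    tgt[g_rows$zyg == 2L] <- "1/1"

    ## truth LOH segments: per window, span of this patient's het sites
    if (!is.null(win)) {
      hets <- g_rows$zyg == 1L
      for (wi in seq_len(nrow(win))) {
        sel <- hets & g_rows$chrom == win$chrom[wi] &
          g_rows$pos >= win$start[wi] & g_rows$pos <= win$end[wi]
        if (!any(sel)) next
        pos <- sort(g_rows$pos[sel])
        truth_loh[[length(truth_loh) + 1L]] <- data.frame(
          patient_id = p, chrom = win$chrom[wi],
          start = pos[1L] - 1L, end = pos[length(pos)],
          n_het_sites = length(pos), stringsAsFactors = FALSE)
      }
    }

    som <- somatic_rows[[p]]
    sdepth <- depth_of(nrow(som))
    salt <- pmax(1L, alt_of(sdepth, cf$somatic_vaf))
    g_df <- data.frame(chrom = g_rows$chrom, pos = g_rows$pos,
                       ref = g_rows$ref, alt = g_rows$alt, gt = ggt,
                       depth = gdepth, alt_depth = galt,
                       stringsAsFactors = FALSE)
    t_df <- rbind(
      data.frame(chrom = g_rows$chrom, pos = g_rows$pos, ref = g_rows$ref,
                 alt = g_rows$alt, gt = tgt, depth = tdepth,
                 alt_depth = talt, stringsAsFactors = FALSE),
      if (nrow(som)) data.frame(chrom = som$chrom, pos = som$pos,
                                ref = som$ref, alt = som$alt, gt = "0/1",
                                depth = sdepth, alt_depth = salt,
                                stringsAsFactors = FALSE))
    writeSimpleVcf(g_df, file.path(outdir, "vcf",
                                   paste0(p, ".germline.vcf")),
                   contig_lengths, sample_id = p)
    writeSimpleVcf(t_df, file.path(outdir, "vcf", paste0(p, ".tumor.vcf")),
                   contig_lengths, sample_id = p)
  }
  truth_loh <- if (length(truth_loh)) do.call(rbind, truth_loh) else
    data.frame(patient_id = character(), chrom = character(),
               start = integer(), end = integer(), n_het_sites = integer())
  truth_loh <- truth_loh[order(truth_loh$patient_id, truth_loh$chrom,
                               truth_loh$start), , drop = FALSE]
  rownames(truth_loh) <- NULL

  ## ---- copy-number segments ------------------------------------------------
  scna_rows <- list()
  for (p in patients) {
    k <- sample(0:2, 1L)
    for (j in seq_len(k)) {
      ch <- sample(contigs, 1L)
      len <- sample(5000:20000, 1L)
      s <- sample(0:(cf$contig_length - len), 1L)
      lr <- sample(c(-1, 1), 1L) * stats::runif(1, 0.4, 1.2)
      scna_rows[[length(scna_rows) + 1L]] <- data.frame(
        patient_id = p, chrom = ch, start = s, end = s + len,
        log2_ratio = round(lr, 3), stringsAsFactors = FALSE)
    }
  }
  scna <- if (length(scna_rows)) do.call(rbind, scna_rows) else
    data.frame(patient_id = character(), chrom = character(),
               start = integer(), end = integer(), log2_ratio = numeric())
  scna_path <- file.path(outdir, "scna_segments.tsv")
  .writeTsv(scna, scna_path)

  ## ---- truth tables and config --------------------------------------------
  carriers <- tapply(priv$patient_id, priv$gene,
                     function(x) length(unique(x)))
  truth_carriers <- data.frame(gene = genes,
                               carrier_count = as.integer(
                                 ifelse(is.na(carriers[genes]), 0L,
                                        carriers[genes])),
                               stringsAsFactors = FALSE)
  paths <- list(reference = fa_path, gene_model = gm_path,
                frequency = freq_path, mappability = mapp_path,
                uniqueness = uniq_path, signatures = sig_path,
                clinical = clin_path, family = fam_path, scna = scna_path,
                vcf_dir = file.path(outdir, "vcf"))
  truth <- list(private = planted, double_hits = truth_dh, loh = truth_loh,
                exposures = truth_expo, gene_carriers = truth_carriers)
  for (nm in names(truth))
    .writeTsv(truth[[nm]], file.path(outdir, "truth", paste0(nm, ".tsv")))
  cf_json <- cf
  jsonlite::write_json(cf_json, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  new("SyntheticBundle", dir = outdir, paths = paths, config = cf,
      truth = truth)
}

#' Reload a previously generated bundle
#'
#' @param dir a directory written by [simulateCohort()].
#' @return a [SyntheticBundle-class].
#' @export
loadBundle <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("not a bundle directory: ", dir)
  cf <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  truth_files <- c("private", "double_hits", "loh", "exposures",
                   "gene_carriers")
  truth <- lapply(truth_files, function(nm)
    .readTsv(file.path(dir, "truth", paste0(nm, ".tsv"))))
  names(truth) <- truth_files
  paths <- list(reference = file.path(dir, "reference.fa"),
                gene_model = file.path(dir, "gene_model.bed"),
                frequency = file.path(dir, "frequency.tsv"),
                mappability = file.path(dir, "mappability.bed"),
                uniqueness = file.path(dir, "uniqueness.bed"),
                signatures = file.path(dir, "signatures.tsv"),
                clinical = file.path(dir, "clinical.tsv"),
                family = file.path(dir, "family.tsv"),
                scna = file.path(dir, "scna_segments.tsv"),
                vcf_dir = file.path(dir, "vcf"))
  new("SyntheticBundle", dir = dir, paths = paths, config = as.list(cf),
      truth = truth)
}

#' Verify the internal consistency of a generated bundle
#'
#' Re-reads every file of the bundle and asserts the truth invariants:
#' every planted variant appears in its carrier's germline VCF with the
#' recorded zygosity and a key that normalizes to the truth key; every
#' germline VCF variant is accounted for (planted, or a known common
#' polymorphism); criterion-3 and criterion-5/6 decoy annotations are
#' really present in the frequency table and tracks; every planted double
#' hit is homozygous-supported in the tumor; and per-sample exposure
#' weights sum to 1.
#'
#' @param bundle a [SyntheticBundle-class] or a bundle directory.
#' @return invisibly, a data.frame report of checks; stops (naming the
#'   offending row) on the first violated invariant.
#' @export
verifyTruth <- function(bundle) {
  if (is.character(bundle)) bundle <- loadBundle(bundle)
  p <- bundlePaths(bundle)
  tr <- bundleTruth(bundle)
  reference <- readReference(p$reference)
  freq <- readFrequencyTable(p$frequency, reference)
  mapp <- readRegionTrack(p$mappability)
  uniq <- readRegionTrack(p$uniqueness)
  planted <- tr$private
  checks <- list()
  note <- function(name, n) checks[[length(checks) + 1L]] <<-
    data.frame(check = name, n = n, stringsAsFactors = FALSE)

  patients <- sort(unique(.readTsv(p$clinical)$patient_id))
  germ <- lapply(patients, function(pid)
    .readVcfCalls(file.path(p$vcf_dir, paste0(pid, ".germline.vcf")),
                  reference))
  names(germ) <- patients

  ## planted rows present with matching zygosity
  for (i in seq_len(nrow(planted))) {
    g <- germ[[planted$patient_id[i]]]
    k <- .keyString(g$chrom, g$pos, g$ref, g$alt)
    tk <- .keyString(planted$chrom[i], planted$pos[i], planted$ref[i],
                     planted$alt[i])
    j <- match(tk, k)
    if (is.na(j))
      stop("truth row ", i, " (", planted$patient_id[i], " ", tk,
           ") missing from germline VCF")
    if (g$zygosity[j] != planted$zygosity[i])
      stop("truth row ", i, " (", tk, "): zygosity mismatch (VCF ",
           g$zygosity[j], ", truth ", planted$zygosity[i], ")")
  }
  note("planted_variants_present", nrow(planted))

  ## every germline VCF variant accounted for
  freq_keys <- freq$keys
  for (pid in patients) {
    g <- germ[[pid]]
    k <- .keyString(g$chrom, g$pos, g$ref, g$alt)
    pl <- planted[planted$patient_id == pid, , drop = FALSE]
    pk <- .keyString(pl$chrom, pl$pos, pl$ref, pl$alt)
    orphan <- !(k %in% pk) & !(k %in% freq_keys)
    if (any(orphan))
      stop("unaccounted germline variant ", k[orphan][1L], " in patient ",
           pid, " (present in VCF but in no truth table)")
  }
  note("no_unaccounted_variants", length(patients))

  ## decoy annotations really present
  mafs <- lookupFrequency(planted$chrom, planted$pos, planted$ref,
                          planted$alt, freq)
  c3 <- planted$role == "decoy_c3"
  if (any(c3) && any(mafs$maf_db1[c3] < 0.005 & mafs$maf_db2[c3] < 0.005))
    stop("criterion-3 decoy has rare annotation in the frequency table")
  m <- trackMinValue(planted$chrom, planted$pos, planted$ref, mapp)
  if (any(m[planted$role == "decoy_c5"] > 0.5))
    stop("criterion-5 decoy not covered by a low-mappability interval")
  u <- trackMinValue(planted$chrom, planted$pos, planted$ref, uniq)
  if (any(u[planted$role == "decoy_c6"] == 1))
    stop("criterion-6 decoy not covered by a non-unique interval")
  if (any(m[planted$is_private] <= 0.5) || any(u[planted$is_private] < 1))
    stop("planted private variant overlaps a decoy annotation hole")
  note("decoy_annotations_consistent", sum(!planted$is_private))

  ## double hits homozygous-supported in tumor
  dh <- tr$double_hits
  for (i in seq_len(nrow(dh))) {
    t <- .readVcfCalls(file.path(p$vcf_dir,
                                 paste0(dh$patient_id[i], ".tumor.vcf")),
                       reference)
    k <- .keyString(t$chrom, t$pos, t$ref, t$alt)
    tk <- .keyString(dh$chrom[i], dh$pos[i], dh$ref[i], dh$alt[i])
    j <- match(tk, k)
    if (is.na(j) || t$zygosity[j] != "hom_alt")
      stop("double-hit truth row ", i, " (", tk,
           ") is not homozygous-alt in the tumor VCF")
  }
  note("double_hits_supported", nrow(dh))

  w <- tr$exposures[, c("sigA", "sigB", "sigC")]
  if (any(abs(rowSums(w) - 1) > 1e-6))
    stop("exposure truth weights do not sum to 1")
  note("exposure_weights_sum_to_1", nrow(w))

  report <- do.call(rbind, checks)
  invisible(report)
}

#' A 24-variant criterion panel
#'
#' A fixed annotated panel for exercising the six-criterion classifier:
#' 4 variants pass all six criteria and 20 decoys each violate exactly one
#' (criteria cycled 1..6). Expected flags are attached as `exp_*` columns.
#'
#' @return data.frame ready for [classifyPrivate()].
#' @export
makeCriterionPanel <- function() {
  base <- data.frame(
    patient_id = sprintf("P%02d", 1:24),
    gene = sprintf("GENE%02d", rep(1:6, 4)),
    consequence = "nonsense", zygosity = "het",
    maf_db1 = 0, maf_db2 = 0, occurrence = 1L,
    mappability = 0.9, unique_locus = TRUE,
    stringsAsFactors = FALSE)
  crit <- c(rep(NA_integer_, 4L), rep(1:6, length.out = 20L))
  for (i in 5:24) {
    switch(crit[i],
           base$consequence[i] <- "synonymous",
           base$zygosity[i] <- "hom_alt",
           base$maf_db1[i] <- 0.006,
           base$occurrence[i] <- 2L,
           base$mappability[i] <- 0.5,
           base$unique_locus[i] <- FALSE)
  }
  for (k in 1:6)
    base[[paste0("exp_c", k)]] <- is.na(crit) | crit != k
  base$exp_private <- is.na(crit)
  base
}
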