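## End-to-end orchestration over an input bundle: cohort classification,
## private-variant calling, LOH/double-hit detection, signature refitting,
## G scores, survival -- each stage a flat TSV so stages stay independently
## inspectable, plus a provenance JSON sufficient to re-execute the run.

#' Pipeline thresholds and settings
#'
#' Every threshold used anywhere in the pipeline, surfaced in one place and
#' echoed to the provenance JSON: population-frequency cutoff 0.5% (strict
#' less-than, in both databases), mappability cutoff 0.5 (strict
#' greater-than), tumor-homozygosity VAF 0.9, minimum informative depth 10,
#' minimum LOH run length 5 sites at VAF deviation 0.25, copy-number
#' thresholds +/-0.3 log2, cluster counts 3/4/5, and a 60-month survival
#' horizon.
#'
#' @param ... overrides for any named default.
#' @return a named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    maf_cutoff = 0.005,
    maf_mode = "and",
    whitelist = defaultWhitelist(),
    mappability_cutoff = 0.5,
    hom_vaf = 0.9,
    min_depth = 10L,
    min_sites = 5L,
    deviation_threshold = 0.25,
    amp_threshold = 0.3,
    del_threshold = -0.3,
    k_values = c(3L, 4L, 5L),
    cluster_seed = 1L,
    km_horizon = 60,
    condition1 = "strict",
    enrichment_signature = NULL)  # default: last signature in the matrix
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown pipeline setting(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

.stageMsg <- function(...) message("[pipeline] ", ...)

#' Run the full analysis pipeline on a bundle directory
#'
#' Expects the file layout written by [simulateCohort()] (equivalently, any
#' bundle with `reference.fa`, `gene_model.bed`, `frequency.tsv`,
#' `mappability.bed`, `uniqueness.bed`, `clinical.tsv`, `family.tsv`,
#' optional `signatures.tsv` and `scna_segments.tsv`, and
#' `vcf/<patient>.germline.vcf` / `vcf/<patient>.tumor.vcf` pairs). Stages
#' run in dependency order; rerunning with unchanged inputs and settings
#' reproduces byte-identical outputs. A missing signature matrix skips the
#' signature stage with a warning; any other stage failure writes a FAILED
#' marker into `outdir` and rethrows.
#'
#' @param bundle_dir input directory.
#' @param outdir output directory for stage TSVs and `provenance.json`.
#' @param config a [pipelineConfig()] list.
#' @return invisibly, a named list of in-memory stage results.
#' @export
runPipeline <- function(bundle_dir, outdir, config = pipelineConfig()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  on_fail <- function(stage, e) {
    writeLines(paste("stage", stage, "failed:", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE)
  }
  unlink(file.path(outdir, "FAILED"))

  path_of <- function(f) file.path(bundle_dir, f)
  reference <- readReference(path_of("reference.fa"))
  gene_model <- readGeneModel(path_of("gene_model.bed"))
  freq <- readFrequencyTable(path_of("frequency.tsv"), reference)
  mapp <- readRegionTrack(path_of("mappability.bed"))
  uniq <- readRegionTrack(path_of("uniqueness.bed"))
  clinical <- .readTsv(path_of("clinical.tsv"))
  family <- .readTsv(path_of("family.tsv"))
  patients <- clinical$patient_id

  ## ---- stage: cohort -------------------------------------------------------
  tryCatch({
    .stageMsg("cohort: classifying ", length(patients), " patients")
    elig <- classifyHdgcCohort(clinical, family, config$condition1)
    comp <- cohortComposition(clinical, elig, family)
    .writeTsv(elig, file.path(outdir, "cohort_eligibility.tsv"))
    .writeTsv(comp, file.path(outdir, "cohort_composition.tsv"))
    res$eligibility <- elig
    res$composition <- comp
  }, error = function(e) on_fail("cohort", e))

  ## ---- read paired VCFs ----------------------------------------------------
  paired <- tryCatch({
    .stageMsg("io: reading ", length(patients), " paired VCFs")
    pl <- lapply(patients, function(p)
      readPairedVcfs(path_of(file.path("vcf", paste0(p, ".germline.vcf"))),
                     path_of(file.path("vcf", paste0(p, ".tumor.vcf"))),
                     reference))
    names(pl) <- patients
    pl
  }, error = function(e) on_fail("io", e))

  ## ---- stage: germline private variants ------------------------------------
  tryCatch({
    germ <- do.call(rbind, lapply(patients, function(p) {
      d <- paired[[p]]
      d <- d[!d$somatic & d$germline_zygosity %in% c("het", "hom_alt"), ,
             drop = FALSE]
      if (nrow(d)) cbind(patient_id = p, d) else NULL
    }))
    key <- .keyString(germ$chrom, germ$pos, germ$ref, germ$alt)
    uk <- !duplicated(key)
    anno <- classifyConsequence(germ[uk, c("chrom", "pos", "ref", "alt")],
                                gene_model, reference)
    idx <- match(key, key[uk])
    germ$gene <- anno$gene[idx]
    germ$consequence <- anno$consequence[idx]
    mafs <- lookupFrequency(germ$chrom, germ$pos, germ$ref, germ$alt, freq)
    germ$maf_db1 <- mafs$maf_db1
    germ$maf_db2 <- mafs$maf_db2
    germ$mappability <- trackMinValue(germ$chrom, germ$pos, germ$ref, mapp)
    germ$unique_locus <- trackMinValue(germ$chrom, germ$pos, germ$ref,
                                       uniq) >= 1
    occ <- table(key)
    germ$occurrence <- as.integer(occ[key])
    germ$zygosity <- germ$germline_zygosity
    calls <- classifyPrivate(germ,
                             whitelist = config$whitelist,
                             maf_cutoff = config$maf_cutoff,
                             maf_mode = config$maf_mode,
                             mappability_cutoff = config$mappability_cutoff)
    d <- as.data.frame(privateCalls(calls))
    .stageMsg("germline: ", sum(d$is_private), " private calls among ",
              nrow(d), " candidates")
    keep <- c("patient_id", "chrom", "pos", "ref", "alt", "gene",
              "consequence", "zygosity", "maf_db1", "maf_db2", "occurrence",
              "mappability", "unique_locus", .PRIVATE_FLAGS, "is_private")
    .writeTsv(d[keep], file.path(outdir, "private_calls.tsv"))
    gf <- geneFrequency(calls, length(patients))
    .writeTsv(gf, file.path(outdir, "gene_frequency.tsv"))
    ptv <- d[d$is_private & isPTV(d$consequence), , drop = FALSE]
    .writeTsv(data.frame(n_private = sum(d$is_private),
                         n_private_ptv = nrow(ptv),
                         n_genes_ptv = length(unique(ptv$gene))),
              file.path(outdir, "ptv_summary.tsv"))
    res$private <- calls
    res$gene_frequency <- gf
  }, error = function(e) on_fail("germline", e))

  ## ---- stage: LOH and double hits ------------------------------------------
  tryCatch({
    loh_all <- do.call(rbind, lapply(patients, function(p) {
      d <- paired[[p]]
      het <- d[!d$somatic & !is.na(d$germline_zygosity) &
                 d$germline_zygosity == "het" & !is.na(d$tumor_vaf), ,
               drop = FALSE]
      het <- het[order(het$chrom, het$pos), , drop = FALSE]
      seg <- callLohSegments(
        data.frame(chrom = het$chrom, pos = het$pos,
                   tumor_vaf = het$tumor_vaf, depth = het$tumor_depth),
        min_sites = config$min_sites,
        deviation_threshold = config$deviation_threshold,
        min_depth = config$min_depth)
      if (nrow(seg)) cbind(patient_id = p, seg) else NULL
    }))
    if (is.null(loh_all))
      loh_all <- data.frame(patient_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            n_het_sites = integer(),
                            median_deviation = numeric())
    priv <- as.data.frame(privateCalls(res$private))
    cand <- priv[priv$is_private & priv$zygosity == "het",
                 c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                   "tumor_zygosity", "tumor_vaf", "tumor_depth"),
                 drop = FALSE]
    cand$germline_zygosity <- "het"
    events <- callDoubleHits(cand, loh_all, hom_vaf = config$hom_vaf,
                             min_depth = config$min_depth)
    summ <- summarizeDoubleHits(events, patients)
    .stageMsg("doublehit: ", nrow(doubleHitEvents(events)), " events, ",
              nrow(loh_all), " LOH segments")
    .writeTsv(loh_all, file.path(outdir, "loh_segments.tsv"))
    .writeTsv(as.data.frame(doubleHitEvents(events)),
              file.path(outdir, "double_hits.tsv"))
    .writeTsv(summ$per_patient, file.path(outdir, "double_hit_per_patient.tsv"))
    .writeTsv(summ$per_gene, file.path(outdir, "double_hit_per_gene.tsv"))
    .writeTsv(summ$overview, file.path(outdir, "double_hit_overview.tsv"))
    res$loh <- loh_all
    res$double_hits <- events
    res$double_hit_summary <- summ
  }, error = function(e) on_fail("doublehit", e))

  ## ---- stage: signatures ---------------------------------------------------
  sig_path <- path_of("signatures.tsv")
  if (!file.exists(sig_path)) {
    warning("no signature matrix found; skipping the signature stage")
  } else tryCatch({
    sigs <- readSignatureMatrix(sig_path)
    snvs <- do.call(rbind, lapply(patients, function(p) {
      d <- paired[[p]]
      d <- d[d$somatic & nchar(d$ref) == 1L & nchar(d$alt) == 1L, ,
             drop = FALSE]
      if (nrow(d)) data.frame(sample_id = p, d[c("chrom", "pos", "ref",
                                                 "alt")]) else NULL
    }))
    catalog <- buildCatalog(snvs, reference, patients)
    expo <- fitExposures(catalog, sigs)
    dom <- assignDominant(expo)
    .stageMsg("signatures: ", sum(catalogCounts(catalog)),
              " somatic SNVs refit over ",
              ncol(signatureProbs(sigs)), " signatures")
    .writeTsv(data.frame(sample_id = rownames(catalogCounts(catalog)),
                         catalogCounts(catalog), check.names = FALSE),
              file.path(outdir, "catalog.tsv"))
    w <- exposureWeights(expo)
    .writeTsv(data.frame(sample_id = rownames(w), w,
                         cosine = reconstructionCosine(expo),
                         dominant = dominantSignature(expo),
                         check.names = FALSE),
              file.path(outdir, "exposures.tsv"))
    .writeTsv(dom$dominance, file.path(outdir, "dominance_table.tsv"))
    n_fit <- sum(!is.na(dominantSignature(expo)))
    k_use <- config$k_values[config$k_values <= n_fit]
    if (length(k_use)) {
      clus <- lapply(k_use, function(k)
        clusterExposures(expo, k, seed = config$cluster_seed))
      cl_df <- data.frame(sample_id = names(clus[[1]]))
      for (i in seq_along(k_use))
        cl_df[[paste0("k", k_use[i])]] <- as.integer(clus[[i]])
      .writeTsv(cl_df, file.path(outdir, "clusters.tsv"))
      res$clusters <- cl_df
    }
    ## dominant-signature enrichment in the EBV-positive subgroup
    target <- config$enrichment_signature
    if (is.null(target))
      target <- utils::tail(colnames(signatureProbs(sigs)), 1L)
    ebv <- clinical$ebv_status[match(rownames(w), clinical$patient_id)]
    flagA <- ifelse(ebv == "unknown", NA, ebv == "positive")
    flagB <- dominantSignature(expo) == target
    enr <- tryCatch(enrichment2x2(flagA, flagB), error = function(e) NULL)
    enr_df <- if (is.null(enr)) {
      data.frame(signature = target, a = NA, b = NA, c = NA, d = NA,
                 p = NA, note = "not testable (zero margin or empty)")
    } else {
      data.frame(signature = target, a = enr$table[1, 1], b = enr$table[1, 2],
                 c = enr$table[2, 1], d = enr$table[2, 2], p = enr$p,
                 note = paste0(enr$n_excluded, " samples excluded"))
    }
    .writeTsv(enr_df, file.path(outdir, "ebv_enrichment.tsv"))
    res$catalog <- catalog
    res$exposures <- expo
    res$dominance <- dom
    res$ebv_enrichment <- enr_df
  }, error = function(e) on_fail("signatures", e))

  ## ---- stage: G scores -----------------------------------------------------
  scna_path <- path_of("scna_segments.tsv")
  if (file.exists(scna_path)) tryCatch({
    scna <- .readTsv(scna_path)
    gs <- geneGScore(scna, gene_model, length(patients),
                     amp_threshold = config$amp_threshold,
                     del_threshold = config$del_threshold)
    .writeTsv(gs, file.path(outdir, "gene_gscore.tsv"))
    res$gscore <- gs
  }, error = function(e) on_fail("gscore", e))

  ## ---- stage: survival -----------------------------------------------------
  tryCatch({
    km <- kmEstimate(clinical$survival_months, clinical$event,
                     horizon = config$km_horizon)
    .writeTsv(km$steps, file.path(outdir, "survival_km.tsv"))
    .writeTsv(km$horizon, file.path(outdir, "survival_horizon.tsv"))
    has_dh <- patients %in%
      doubleHitEvents(res$double_hits)$patient_id
    lr_df <- if (length(unique(has_dh)) == 2L) {
      lr <- logrankTest(clinical$survival_months, clinical$event, has_dh)
      data.frame(grouping = "double_hit_present", statistic = lr$statistic,
                 df = lr$df, p = lr$p)
    } else {
      data.frame(grouping = "double_hit_present", statistic = NA,
                 df = NA, p = NA)
    }
    .writeTsv(lr_df, file.path(outdir, "logrank.tsv"))
    res$survival <- km
    res$logrank <- lr_df
  }, error = function(e) on_fail("survival", e))

  ## ---- provenance ----------------------------------------------------------
  inputs <- list.files(bundle_dir, recursive = TRUE, full.names = TRUE)
  inputs <- inputs[!grepl("^truth/", sub(paste0("^", bundle_dir, "/?"), "",
                                         inputs))]
  prov <- list(
    package = "HDGCprofiler",
    version = as.character(utils::packageVersion("HDGCprofiler")),
    bundle_dir = bundle_dir,
    settings = config,
    input_md5 = as.list(tools::md5sum(sort(inputs))))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
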