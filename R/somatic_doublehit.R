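## LOH segment calling from tumor allele fractions, double-hit event
## detection, and simplified gene-level G-score summaries of copy-number
## segments.

#' Call LOH segments from tumor allele fractions at germline het sites
#'
#' Scans germline-heterozygous sites in position order and reports maximal
#' runs of at least `min_sites` consecutive informative sites (tumor depth >=
#' `min_depth`) whose tumor variant allele fraction deviates from 0.5 by at
#' least `deviation_threshold`. Sites below `min_depth` are skipped without
#' breaking a run; a balanced informative site ends the run. The reported
#' segment is the 0-based half-open span from the first to the last site of
#' the run.
#'
#' This caller operates on allele fractions alone; tumor purity is not
#' modeled, so thresholds assume high-purity tumors.
#'
#' @param sites data.frame of germline-het sites for one sample/contig pair
#'   or with a `chrom` column, sorted by position within chrom; columns
#'   `pos` (1-based), `tumor_vaf`, `depth`.
#' @param min_sites minimum run length (default 5).
#' @param deviation_threshold minimum `|vaf - 0.5|` (default 0.25).
#' @param min_depth minimum informative depth (default 10).
#' @return data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open), `n_het_sites`, `median_deviation`.
#' @export
callLohSegments <- function(sites, min_sites = 5L, deviation_threshold = 0.25,
                            min_depth = 10L) {
  .assertColumns(sites, c("pos", "tumor_vaf", "depth"), "het sites")
  if (!"chrom" %in% names(sites)) sites$chrom <- "."
  out <- lapply(split(sites, sites$chrom), function(s) {
    if (is.unsorted(s$pos, strictly = FALSE))
      stop("het sites must be sorted by position within each contig")
    inf <- !is.na(s$tumor_vaf) & !is.na(s$depth) & s$depth >= min_depth
    s <- s[inf, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    dev <- abs(s$tumor_vaf - 0.5)
    r <- rle(dev >= deviation_threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_sites
    if (!any(keep)) return(NULL)
    data.frame(chrom = s$chrom[1L],
               start = s$pos[starts[keep]] - 1L,
               end = s$pos[ends[keep]],
               n_het_sites = r$lengths[keep],
               median_deviation = vapply(which(keep), function(i)
                 stats::median(dev[starts[i]:ends[i]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_het_sites = integer(), median_deviation = numeric())
  rownames(out) <- NULL
  out
}

#' Call double-hit events (germline het become homozygous in the tumor)
#'
#' A double-hit event is emitted for a germline-heterozygous variant when at
#' least one of three clauses holds in the paired tumor:
#' \enumerate{
#'   \item the tumor genotype itself is homozygous-alt (`genotype_homozygous`);
#'   \item the tumor VAF is at least `hom_vaf` at depth >= `min_depth`
#'     (`vaf_threshold`);
#'   \item the variant lies inside a called LOH segment and its tumor VAF
#'     exceeds 0.5, i.e. the retained allele is the alternate (`loh_overlap`).
#' }
#' Evidence tags record every clause that fired. Variants with no tumor
#' genotype and no VAF are skipped with a warning.
#'
#' @param calls data.frame of germline-heterozygous calls: `patient_id`,
#'   `gene`, `chrom`, `pos`, `ref`, `alt`, `germline_zygosity` (must all be
#'   `"het"`), `tumor_zygosity`, `tumor_vaf`, `tumor_depth`.
#' @param loh_segments data.frame per patient: `patient_id`, `chrom`,
#'   `start`, `end` (0-based half-open), e.g. from [callLohSegments()].
#' @param hom_vaf VAF at or above which the tumor is considered homozygous
#'   (default 0.9).
#' @param min_depth minimum tumor depth for the VAF clause (default 10).
#' @return a [DoubleHitSet-class]; one event per (patient, variant).
#' @export
callDoubleHits <- function(calls, loh_segments = NULL, hom_vaf = 0.9,
                           min_depth = 10L) {
  .assertColumns(calls, c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                          "germline_zygosity", "tumor_zygosity", "tumor_vaf",
                          "tumor_depth"), "germline calls")
  if (nrow(calls) && any(calls$germline_zygosity != "het"))
    stop("double-hit calling requires germline-heterozygous calls only")
  no_tumor <- is.na(calls$tumor_zygosity) & is.na(calls$tumor_vaf)
  if (any(no_tumor)) {
    warning(sum(no_tumor), " variant(s) skipped: no tumor genotype or VAF")
    calls <- calls[!no_tumor, , drop = FALSE]
  }
  e_gt <- !is.na(calls$tumor_zygosity) & calls$tumor_zygosity == "hom_alt"
  e_vaf <- !is.na(calls$tumor_vaf) & !is.na(calls$tumor_depth) &
    calls$tumor_vaf >= hom_vaf & calls$tumor_depth >= min_depth
  e_loh <- rep(FALSE, nrow(calls))
  if (!is.null(loh_segments) && nrow(loh_segments) && nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      seg <- loh_segments[loh_segments$patient_id == calls$patient_id[i] &
                            loh_segments$chrom == calls$chrom[i] &
                            loh_segments$start < calls$pos[i] &
                            loh_segments$end >= calls$pos[i], , drop = FALSE]
      e_loh[i] <- nrow(seg) > 0L && !is.na(calls$tumor_vaf[i]) &&
        calls$tumor_vaf[i] > 0.5
    }
  }
  hit <- e_gt | e_vaf | e_loh
  ev <- vapply(which(hit), function(i)
    paste(c("genotype_homozygous", "vaf_threshold",
            "loh_overlap")[c(e_gt[i], e_vaf[i], e_loh[i])], collapse = ","),
    character(1))
  d <- calls[hit, c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                    "germline_zygosity", "tumor_vaf", "tumor_depth"),
             drop = FALSE]
  d$evidence <- ev
  key <- paste(d$patient_id, .keyString(d$chrom, d$pos, d$ref, d$alt))
  d <- d[!duplicated(key), , drop = FALSE]
  rownames(d) <- NULL
  new("DoubleHitSet", events = S4Vectors::DataFrame(d))
}

#' Summarize double-hit events per patient and per gene
#'
#' @param events a [DoubleHitSet-class].
#' @param patient_ids all sequenced patients (so zero-event patients appear
#'   in the per-patient table and the all-patients mean).
#' @return list with `per_patient` (patient_id, n_events), `per_gene` (gene,
#'   n_events, n_patients), and `overview`: total events, number of
#'   event-bearing patients, the share of event-bearing patients with 1-2
#'   events (one-decimal percent), and the mean and range of event counts
#'   over both denominators (event-bearing patients and all patients).
#' @export
summarizeDoubleHits <- function(events, patient_ids) {
  d <- as.data.frame(doubleHitEvents(events))
  counts <- table(factor(d$patient_id, levels = patient_ids))
  per_patient <- data.frame(patient_id = names(counts),
                            n_events = as.integer(counts),
                            stringsAsFactors = FALSE)
  per_gene <- if (nrow(d)) {
    g <- stats::aggregate(list(n_events = d$pos), by = list(gene = d$gene),
                          FUN = length)
    g$n_patients <- as.integer(tapply(d$patient_id, d$gene,
                                      function(p) length(unique(p)))[g$gene])
    g[order(-g$n_events, g$gene), , drop = FALSE]
  } else data.frame(gene = character(), n_events = integer(),
                    n_patients = integer())
  bearing <- per_patient$n_events[per_patient$n_events > 0L]
  overview <- data.frame(
    n_events = nrow(d),
    n_patients_with_events = length(bearing),
    n_patients_total = length(patient_ids),
    pct_bearing_with_1_2 = if (length(bearing))
      carrierPercent(sum(bearing %in% 1:2), length(bearing)) else NA_real_,
    mean_events_bearing = if (length(bearing)) mean(bearing) else NA_real_,
    mean_events_all = mean(per_patient$n_events),
    max_events = if (nrow(per_patient)) max(per_patient$n_events) else 0L)
  rownames(per_gene) <- NULL
  list(per_patient = per_patient, per_gene = per_gene, overview = overview)
}

#' Gene-level G-score summary of copy-number segments
#'
#' For each gene, the amplification (deletion) frequency is the fraction of
#' patients with an overlapping segment at `log2_ratio >= amp_threshold`
#' (`<= del_threshold`), and the G score is that frequency multiplied by the
#' mean absolute log2 ratio of the qualifying overlapping segments. This is
#' a deliberately simplified frequency-times-amplitude surrogate, not the
#' GISTIC significance statistic; it consumes externally produced segments.
#'
#' @param segments data.frame: `patient_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `log2_ratio`.
#' @param gene_model GRanges from [readGeneModel()].
#' @param n_patients cohort denominator.
#' @param amp_threshold,del_threshold log2-ratio thresholds (default +0.3 /
#'   -0.3).
#' @return data.frame per gene: `amp_freq`, `del_freq`, `g_amp`, `g_del`
#'   (zeros where no segment overlaps).
#' @export
geneGScore <- function(segments, gene_model, n_patients,
                       amp_threshold = 0.3, del_threshold = -0.3) {
  if (n_patients <= 0L) stop("n_patients must be > 0")
  genes <- sort(unique(gene_model$gene))
  span <- vapply(genes, function(g) {
    ex <- gene_model[gene_model$gene == g]
    c(min(GenomicRanges::start(ex)), max(GenomicRanges::end(ex)))
  }, integer(2))
  chrom <- vapply(genes, function(g)
    as.character(GenomicRanges::seqnames(gene_model[gene_model$gene == g]))[1L],
    character(1))
  res <- lapply(seq_along(genes), function(i) {
    ov <- segments[segments$chrom == chrom[i] &
                     segments$start < span[2L, i] &
                     segments$end >= span[1L, i], , drop = FALSE]
    amp <- ov[ov$log2_ratio >= amp_threshold, , drop = FALSE]
    del <- ov[ov$log2_ratio <= del_threshold, , drop = FALSE]
    amp_freq <- length(unique(amp$patient_id)) / n_patients
    del_freq <- length(unique(del$patient_id)) / n_patients
    data.frame(gene = genes[i],
               amp_freq = amp_freq, del_freq = del_freq,
               g_amp = if (nrow(amp)) amp_freq * mean(abs(amp$log2_ratio)) else 0,
               g_del = if (nrow(del)) del_freq * mean(abs(del$log2_ratio)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
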