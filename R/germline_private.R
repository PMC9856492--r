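## Consequence classification, PTV calling, and the six-criterion private
## germline variant classifier.

#' Consequence classes
#'
#' The fixed vocabulary used throughout: `nonsense`, `splice_site`,
#' `frameshift_indel`, `inframe_indel`, `missense`, `synonymous`, `other`.
#' @export
consequenceClasses <- function() {
  c("nonsense", "splice_site", "frameshift_indel", "inframe_indel",
    "missense", "synonymous", "other")
}

#' Is a consequence class a premature truncating variant (PTV)?
#'
#' PTVs are frameshift indels, nonsense alterations and splice-site
#' alterations.
#'
#' @param consequence character vector of consequence classes.
#' @return logical vector.
#' @export
isPTV <- function(consequence) {
  bad <- setdiff(unique(consequence), consequenceClasses())
  if (length(bad)) stop("unknown consequence class: ", paste(bad, collapse = ", "))
  consequence %in% c("frameshift_indel", "nonsense", "splice_site")
}

## Precompute per-gene structures from the gene model: genomically sorted
## exons, transcription-ordered CDS sequence, genomic<->CDS maps and the
## +/-2 bp intronic splice windows.
.geneIndex <- function(gene_model, reference) {
  genes <- sort(unique(gene_model$gene))
  idx <- lapply(genes, function(g) {
    ex <- gene_model[gene_model$gene == g]
    strand <- unique(as.character(GenomicRanges::strand(ex)))
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stop("gene ", g, " lacks a single defined strand in the gene model")
    chrom <- unique(as.character(GenomicRanges::seqnames(ex)))
    if (length(chrom) != 1L) stop("gene ", g, " spans multiple contigs")
    ord <- order(ex$exon_rank)
    ex <- ex[ord]
    starts <- GenomicRanges::start(ex); ends <- GenomicRanges::end(ex)
    ## transcription order: rank order must walk the genome 5'->3' on strand
    widths <- ends - starts + 1L
    cds_parts <- vapply(seq_along(ex), function(i)
      .refSlice(reference, chrom, starts[i], ends[i]), character(1))
    if (strand == "-")
      cds_parts <- vapply(cds_parts, function(s)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
        character(1))
    cds_seq <- paste(cds_parts, collapse = "")
    cum_before <- cumsum(c(0L, widths))[seq_along(widths)]
    ## splice windows: 2 intronic bases each side of every intron
    gs <- sort(starts); ge <- sort(ends)
    windows <- NULL
    if (length(gs) > 1L) {
      int_start <- ge[-length(ge)] + 1L
      int_end <- gs[-1L] - 1L
      keep <- int_end >= int_start
      int_start <- int_start[keep]; int_end <- int_end[keep]
      if (length(int_start)) {
        donor <- cbind(int_start, pmin(int_start + 1L, int_end))
        accept <- cbind(pmax(int_end - 1L, int_start), int_end)
        windows <- rbind(donor, accept)
      }
    }
    list(gene = g, chrom = chrom, strand = strand,
         exon_start = starts, exon_end = ends, cum_before = cum_before,
         cds_seq = cds_seq, span_start = min(starts), span_end = max(ends),
         splice = windows)
  })
  names(idx) <- genes
  idx
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## genomic position -> 1-based CDS coordinate (NA if intronic)
.cdsCoord <- function(gi, pos) {
  hit <- which(gi$exon_start <= pos & gi$exon_end >= pos)
  if (!length(hit)) return(NA_integer_)
  i <- hit[1L]
  if (gi$strand == "+") gi$cum_before[i] + (pos - gi$exon_start[i]) + 1L
  else gi$cum_before[i] + (gi$exon_end[i] - pos) + 1L
}

.classifyOne <- function(chrom, pos, ref, alt, gi) {
  span_end <- pos + nchar(ref) - 1L
  in_cds <- any(gi$exon_start <= span_end & gi$exon_end >= pos)
  if (in_cds) {
    if (nchar(ref) != nchar(alt)) {
      if (abs(nchar(ref) - nchar(alt)) %% 3L == 0L) return("inframe_indel")
      return("frameshift_indel")
    }
    if (nchar(ref) == 1L) {
      cpos <- .cdsCoord(gi, pos)
      if (is.na(cpos)) return("other")
      rb <- ref; ab <- alt
      if (gi$strand == "-") { rb <- .COMPLEMENT[[rb]]; ab <- .COMPLEMENT[[ab]] }
      ci <- (cpos - 1L) %/% 3L
      if (3L * ci + 3L > nchar(gi$cds_seq))
        stop("incomplete terminal codon in gene ", gi$gene,
             "; CDS length is not a multiple of 3")
      codon <- substr(gi$cds_seq, 3L * ci + 1L, 3L * ci + 3L)
      off <- cpos - 3L * ci
      stopifnot(substr(codon, off, off) == rb)
      alt_codon <- codon
      substr(alt_codon, off, off) <- ab
      code <- Biostrings::GENETIC_CODE
      ref_aa <- code[[codon]]; alt_aa <- code[[alt_codon]]
      if (alt_aa == "*" && ref_aa != "*") return("nonsense")
      if (alt_aa == ref_aa) return("synonymous")
      return("missense")
    }
    ## multi-base substitution inside CDS: treat as missense-like
    return("missense")
  }
  if (!is.null(gi$splice)) {
    hit <- any(gi$splice[, 1L] <= span_end & gi$splice[, 2L] >= pos)
    if (hit) return("splice_site")
  }
  "other"
}

#' Classify coding consequence of variants against a gene model
#'
#' A variant is assigned to the gene whose span (first to last CDS exon,
#' introns included) contains it; overlap ties go to the gene with a CDS
#' overlap, then alphabetically. Rules: an intronic position within 2 bp of
#' an exon/intron boundary is `splice_site`; a coding indel is
#' `frameshift_indel` when its length change is not divisible by 3, else
#' `inframe_indel`; a coding SNV is translated in its codon (strand-aware)
#' and called `nonsense` (creates a stop), `synonymous`, or `missense`;
#' anything else is `other`.
#'
#' @param variants data.frame with normalized `chrom`, `pos`, `ref`, `alt`.
#' @param gene_model GRanges from [readGeneModel()].
#' @param reference DNAStringSet from [readReference()].
#' @return data.frame with `gene` (empty string where no gene overlaps) and
#'   `consequence`.
#' @export
classifyConsequence <- function(variants, gene_model, reference) {
  .assertColumns(variants, c("chrom", "pos", "ref", "alt"), "variants")
  idx <- .geneIndex(gene_model, reference)
  spans <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L))
  gene_spans <- GenomicRanges::GRanges(
    vapply(idx, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(idx, `[[`, integer(1), "span_start"),
                     vapply(idx, `[[`, integer(1), "span_end")))
  hits <- GenomicRanges::findOverlaps(spans, gene_spans)
  gene <- character(nrow(variants)); cons <- character(nrow(variants))
  by_var <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (i in seq_len(nrow(variants))) {
    cand <- by_var[[as.character(i)]]
    if (is.null(cand)) { gene[i] <- ""; cons[i] <- "other"; next }
    classed <- vapply(cand, function(j)
      .classifyOne(variants$chrom[i], variants$pos[i],
                   variants$ref[i], variants$alt[i], idx[[j]]), character(1))
    pick <- order(classed == "other", names(idx)[cand])[1L]
    gene[i] <- names(idx)[cand][pick]
    cons[i] <- classed[pick]
  }
  data.frame(gene = gene, consequence = cons, stringsAsFactors = FALSE)
}

#' Six-criterion private-variant classification
#'
#' A germline variant is private when all six criteria hold:
#' \enumerate{
#'   \item its consequence class is in the whitelist;
#'   \item it is heterozygous in the germline;
#'   \item its population allele frequency is below `maf_cutoff` (strict) in
#'     both population databases (`maf_mode = "and"`, the default) or in at
#'     least one (`"or"`);
#'   \item it occurs in exactly one patient of the cohort;
#'   \item its mappability score exceeds `mappability_cutoff` (strict);
#'   \item it maps to a single genomic locus.
#' }
#'
#' The default whitelist contains the three PTV classes plus missense, since
#' missense alterations are reported among private germline variants; a
#' strict PTV-only whitelist is available by passing
#' `whitelist = ptvWhitelist()`.
#'
#' @param annotated data.frame with one candidate call per row and columns
#'   `patient_id`, `gene`, `consequence`, `zygosity`, `maf_db1`, `maf_db2`,
#'   `occurrence` (number of cohort patients carrying the variant, >= 1),
#'   `mappability`, `unique_locus`.
#' @param whitelist consequence classes satisfying criterion 1.
#' @param maf_cutoff population-frequency threshold (default 0.005, i.e.
#'   0.5\%; comparison is strict `<`).
#' @param maf_mode `"and"` (rare in both databases) or `"or"`.
#' @param mappability_cutoff mappability threshold (strict `>`).
#' @return a [PrivateCallSet-class] carrying the input plus the six flags
#'   `c1_consequence`..`c6_unique` and `is_private`.
#' @export
classifyPrivate <- function(annotated,
                            whitelist = defaultWhitelist(),
                            maf_cutoff = 0.005,
                            maf_mode = c("and", "or"),
                            mappability_cutoff = 0.5) {
  maf_mode <- match.arg(maf_mode)
  need <- c("patient_id", "gene", "consequence", "zygosity", "maf_db1",
            "maf_db2", "occurrence", "mappability", "unique_locus")
  for (col in need) {
    if (!col %in% names(annotated))
      stop("annotation is missing required field: ", col)
    if (col %in% c("maf_db1", "maf_db2", "mappability", "occurrence") &&
        any(is.na(annotated[[col]])))
      stop("annotation field has missing values: ", col)
  }
  if (any(annotated$occurrence < 1L))
    stop("occurrence counts must be >= 1 (the carrier itself counts)")
  d <- S4Vectors::DataFrame(annotated)
  d$c1_consequence <- annotated$consequence %in% whitelist
  d$c2_het <- annotated$zygosity == "het"
  rare1 <- annotated$maf_db1 < maf_cutoff
  rare2 <- annotated$maf_db2 < maf_cutoff
  d$c3_rare <- if (maf_mode == "and") rare1 & rare2 else rare1 | rare2
  d$c4_singleton <- annotated$occurrence == 1L
  d$c5_mappable <- annotated$mappability > mappability_cutoff
  d$c6_unique <- as.logical(annotated$unique_locus)
  d$is_private <- d$c1_consequence & d$c2_het & d$c3_rare &
    d$c4_singleton & d$c5_mappable & d$c6_unique
  new("PrivateCallSet", calls = d)
}

#' @rdname classifyPrivate
#' @export
defaultWhitelist <- function() {
  c("frameshift_indel", "nonsense", "splice_site", "missense")
}

#' @rdname classifyPrivate
#' @export
ptvWhitelist <- function() {
  c("frameshift_indel", "nonsense", "splice_site")
}

#' Per-gene carrier frequency of private variants
#'
#' A patient contributes at most once to a gene's carrier count regardless
#' of how many qualifying variants they carry in it.
#'
#' @param calls a [PrivateCallSet-class] or a data.frame with `patient_id`,
#'   `gene`, `is_private`.
#' @param cohort_size number of patients in the denominator.
#' @return data.frame with `gene`, `carrier_count`, `cohort_size`, `percent`
#'   (one decimal), sorted by decreasing frequency then gene name.
#' @export
geneFrequency <- function(calls, cohort_size) {
  if (cohort_size == 0L) stop("cohort_size must be > 0")
  if (is(calls, "PrivateCallSet")) calls <- as.data.frame(privateCalls(calls))
  d <- calls[calls$is_private & nzchar(calls$gene), , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(gene = character(), carrier_count = integer(),
                      cohort_size = integer(), percent = numeric()))
  carriers <- tapply(d$patient_id, d$gene, function(p) length(unique(p)))
  out <- data.frame(gene = names(carriers),
                    carrier_count = as.integer(carriers),
                    cohort_size = cohort_size,
                    percent = carrierPercent(as.integer(carriers), cohort_size),
                    stringsAsFactors = FALSE)
  out[order(-out$carrier_count, out$gene), , drop = FALSE]
}
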