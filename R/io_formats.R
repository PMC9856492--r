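## I/O and variant-representation normalization.
##
## Coordinate conventions, fixed at this boundary and nowhere else:
##   * VCF and all in-memory variant positions: 1-based, inclusive.
##   * BED-like tracks and the gene model: 0-based, half-open; converted to
##     1-based GRanges on load.

#' Read a reference FASTA as a DNAStringSet
#'
#' Contig names are truncated at the first whitespace, matching how VCF and
#' BED files refer to them.
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet] named by contig.
#' @export
readReference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

.refSlice <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference))
    stop("unknown contig: ", chrom)
  w <- length(reference[[chrom]])
  if (start < 1 || end > w)
    stop("coordinates ", start, "-", end, " outside contig ", chrom,
         " (length ", w, ")")
  as.character(Biostrings::subseq(reference[[chrom]], start, end))
}

#' Normalize a variant to its left-aligned, parsimonious representation
#'
#' Applies the standard allele-normalization algorithm: shared trailing bases
#' are trimmed (extending the window leftwards through the reference whenever
#' an allele would become empty, which slides indels to their leftmost
#' equivalent position), then shared leading bases are trimmed down to the
#' single anchor base indels require. SNVs pass through unchanged. The result
#' is idempotent, and two equivalent input representations always map to the
#' same output.
#'
#' @param chrom,pos,ref,alt vectors describing one variant per element;
#'   `pos` is the 1-based position of the first reference base.
#' @param reference a [Biostrings::DNAStringSet] as from [readReference()].
#' @return a data.frame with normalized `chrom`, `pos`, `ref`, `alt`.
#' @export
normalizeVariant <- function(chrom, pos, ref, alt, reference) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  out_pos <- integer(n); out_ref <- character(n); out_alt <- character(n)
  for (i in seq_len(n)) {
    p <- pos[i]; r <- ref[i]; a <- alt[i]; ch <- chrom[i]
    if (!nzchar(r) || !nzchar(a))
      stop("empty allele at ", ch, ":", p)
    if (r == a)
      stop("ref and alt alleles are identical at ", ch, ":", p)
    seen <- .refSlice(reference, ch, p, p + nchar(r) - 1L)
    if (seen != r)
      stop("reference mismatch at ", ch, ":", p,
           " (expected ", seen, ", got ", r, ")")
    repeat {
      nr <- nchar(r); na <- nchar(a)
      if (nr > 0 && na > 0 &&
          substr(r, nr, nr) == substr(a, na, na) && (nr > 1 || na > 1)) {
        r <- substr(r, 1L, nr - 1L)
        a <- substr(a, 1L, na - 1L)
        if (!nzchar(r) || !nzchar(a)) {
          if (p == 1L)
            stop("cannot left-extend variant past the start of contig ", ch)
          p <- p - 1L
          base <- .refSlice(reference, ch, p, p)
          r <- paste0(base, r)
          a <- paste0(base, a)
        }
      } else break
    }
    while (nchar(r) >= 2 && nchar(a) >= 2 &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    out_pos[i] <- p; out_ref[i] <- r; out_alt[i] <- a
  }
  data.frame(chrom = chrom, pos = out_pos, ref = out_ref, alt = out_alt,
             stringsAsFactors = FALSE)
}

## GT string -> zygosity w.r.t. a given (1-based) alt index
.zygosityFromGT <- function(gt, alt_index) {
  vapply(seq_along(gt), function(i) {
    g <- gt[i]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return("missing")
    k <- sum(alleles == as.character(alt_index[i]))
    if (k == 0L) "hom_ref" else if (k == length(alleles)) "hom_alt" else "het"
  }, character(1))
}

## Read a single-sample VCF into a flat call table with normalized keys.
## Multi-allelic records are expanded to bi-allelic rows before
## normalization; AD is taken per expanded alt.
.readVcfCalls <- function(path, reference) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "local")),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e)))
  if (ncol(v) != 1L)
    stop("expected exactly 1 sample in ", path, ", found ", ncol(v))
  if (!"GT" %in% names(VariantAnnotation::geno(v)))
    stop("VCF ", path, " has no GT genotype field")
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
  alt_index <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  ve <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(ve)
  gt <- as.character(VariantAnnotation::geno(ve)$GT[, 1L])
  geno_names <- names(VariantAnnotation::geno(ve))
  if ("AD" %in% geno_names) {
    ad <- VariantAnnotation::geno(ve)$AD
    ref_depth <- as.numeric(ad[, 1L, 1L])
    alt_depth <- as.numeric(ad[, 1L, 2L])
  } else {
    ref_depth <- rep(NA_real_, length(gt))
    alt_depth <- rep(NA_real_, length(gt))
  }
  if ("DP" %in% geno_names) {
    depth <- as.numeric(VariantAnnotation::geno(ve)$DP[, 1L])
  } else {
    depth <- ref_depth + alt_depth
  }
  alt_chr <- as.character(VariantAnnotation::alt(ve))
  keep <- nzchar(alt_chr) & alt_chr != "*" & alt_chr != "."
  key <- normalizeVariant(as.character(GenomicRanges::seqnames(rr))[keep],
                          GenomicRanges::start(rr)[keep],
                          as.character(VariantAnnotation::ref(ve))[keep],
                          alt_chr[keep], reference)
  depth <- depth[keep]; alt_depth <- alt_depth[keep]
  zyg <- .zygosityFromGT(gt[keep], alt_index[keep])
  bad <- !is.na(alt_depth) & !is.na(depth) & alt_depth > depth
  if (any(bad)) stop("AD exceeds DP at ", key$chrom[bad][1], ":", key$pos[bad][1])
  vaf <- ifelse(!is.na(depth) & depth > 0, alt_depth / depth, NA_real_)
  data.frame(chrom = key$chrom, pos = key$pos, ref = key$ref, alt = key$alt,
             zygosity = zyg, depth = depth, alt_depth = alt_depth, vaf = vaf,
             stringsAsFactors = FALSE)
}

#' Read a paired germline/tumor VCF into one per-variant table
#'
#' Keys are normalized with [normalizeVariant()] so germline and tumor
#' records pair correctly whatever their on-disk representation. The result
#' is the set union of both files: records seen only in the tumor are flagged
#' `somatic`; germline-only records carry NA tumor fields.
#'
#' @param germline_path,tumor_path single-sample VCF 4.2 files with GT (and
#'   ideally AD/DP) FORMAT fields.
#' @param reference a [Biostrings::DNAStringSet].
#' @return data.frame with one row per distinct normalized variant: key
#'   columns, `germline_*` and `tumor_*` genotype fields (`zygosity`,
#'   `depth`, `alt_depth`, `vaf`), and a logical `somatic` column.
#' @export
readPairedVcfs <- function(germline_path, tumor_path, reference) {
  g <- .readVcfCalls(germline_path, reference)
  t <- .readVcfCalls(tumor_path, reference)
  gk <- .keyString(g$chrom, g$pos, g$ref, g$alt)
  tk <- .keyString(t$chrom, t$pos, t$ref, t$alt)
  if (anyDuplicated(gk)) stop("duplicate variant in ", germline_path)
  if (anyDuplicated(tk)) stop("duplicate variant in ", tumor_path)
  all_keys <- union(gk, tk)
  gi <- match(all_keys, gk); ti <- match(all_keys, tk)
  take <- function(df, idx, col) df[[col]][idx]
  base_from <- ifelse(is.na(gi), ti + nrow(g), gi)
  pool <- rbind(g[c("chrom", "pos", "ref", "alt")],
                t[c("chrom", "pos", "ref", "alt")])
  out <- data.frame(
    chrom = pool$chrom[base_from], pos = pool$pos[base_from],
    ref = pool$ref[base_from], alt = pool$alt[base_from],
    germline_zygosity = ifelse(is.na(gi), NA_character_, take(g, gi, "zygosity")),
    germline_depth = take(g, gi, "depth"),
    germline_alt_depth = take(g, gi, "alt_depth"),
    germline_vaf = take(g, gi, "vaf"),
    tumor_zygosity = ifelse(is.na(ti), NA_character_, take(t, ti, "zygosity")),
    tumor_depth = take(t, ti, "depth"),
    tumor_alt_depth = take(t, ti, "alt_depth"),
    tumor_vaf = take(t, ti, "vaf"),
    somatic = is.na(gi),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
}

#' Write a minimal single-sample VCF 4.2
#'
#' Emits GT:AD:DP records with a fixed, timestamp-free header so identical
#' inputs always produce byte-identical files.
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gt`
#'   (VCF genotype string), `depth`, `alt_depth`.
#' @param path output path.
#' @param contigs named integer vector of contig lengths.
#' @param sample_id sample column name.
#' @export
writeSimpleVcf <- function(df, path, contigs, sample_id = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  ref_depth <- as.integer(df$depth) - as.integer(df$alt_depth)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
                  df$chrom, as.integer(df$pos), df$ref, df$alt, df$gt,
                  ref_depth, as.integer(df$alt_depth), as.integer(df$depth))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED-like value track
#'
#' BED4 (`chrom`, `start`, `end`, `value`), 0-based half-open, converted to a
#' 1-based GRanges. Used for the mappability and locus-uniqueness tracks.
#'
#' @param path BED file (no header).
#' @return [GenomicRanges::GRanges] with a numeric `value` column.
#' @export
readRegionTrack <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(d)[1:4] <- c("chrom", "start", "end", "value")
  if (any(d$start >= d$end)) stop("track intervals must have start < end")
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$start + 1L, d$end),
                               value = as.numeric(d$value))
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop("track intervals overlap within a contig")
  gr
}

#' Minimum track value over a variant's reference span
#'
#' Multi-base variants take the minimum value across every base they touch;
#' bases not covered by any interval take `default`.
#'
#' @param chrom,pos,ref variant key columns (1-based, `ref` gives the span).
#' @param track GRanges from [readRegionTrack()].
#' @param default value assumed where the track has no interval.
#' @return numeric vector of per-variant minima.
#' @export
trackMinValue <- function(chrom, pos, ref, track, default = 1) {
  spans <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(pos, pos + nchar(ref) - 1L))
  hits <- GenomicRanges::findOverlaps(spans, track)
  out <- rep(as.numeric(default), length(spans))
  if (length(hits)) {
    v <- tapply(track$value[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), min)
    idx <- as.integer(names(v))
    ## a partial overlap leaves uncovered bases at the default value
    covered <- tapply(IRanges::width(IRanges::pintersect(
      IRanges::ranges(spans)[S4Vectors::queryHits(hits)],
      IRanges::ranges(track)[S4Vectors::subjectHits(hits)])),
      S4Vectors::queryHits(hits), sum)
    full <- covered >= IRanges::width(IRanges::ranges(spans))[idx]
    out[idx] <- ifelse(full, v, pmin(v, default))
  }
  out
}

#' Read a gene model from a BED6-like file
#'
#' One row per CDS exon: `chrom`, `start` (0-based), `end`, `gene`,
#' `exon_rank` (1-based in transcription order), `strand`. Coding frame is
#' derived from cumulative exon lengths in rank order.
#'
#' @param path TSV/BED path (no header).
#' @return [GenomicRanges::GRanges] with `gene` and `exon_rank` columns.
#' @export
readGeneModel <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(d)[1:6] <- c("chrom", "start", "end", "gene", "exon_rank", "strand")
  if (!all(d$strand %in% c("+", "-")))
    stop("gene model strand must be + or - for every CDS exon")
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                         strand = d$strand, gene = d$gene,
                         exon_rank = as.integer(d$exon_rank))
}

#' Read a population allele-frequency table
#'
#' TSV with header `chrom`, `pos`, `ref`, `alt`, `freq1`, `freq2` (the two
#' population databases, e.g. a 1000 Genomes-like and a Chinese
#' Millionome-like resource). Keys are normalized on load so lookups are
#' representation-independent.
#'
#' @param path TSV path.
#' @param reference DNAStringSet used for key normalization.
#' @return an object of class `frequencyTable` for [lookupFrequency()].
#' @export
readFrequencyTable <- function(path, reference) {
  d <- .readTsv(path)
  .assertColumns(d, c("chrom", "pos", "ref", "alt", "freq1", "freq2"),
                 "frequency table")
  if (any(d$freq1 < 0 | d$freq1 > 1 | d$freq2 < 0 | d$freq2 > 1))
    stop("allele frequencies must lie in [0, 1]")
  key <- normalizeVariant(d$chrom, d$pos, d$ref, d$alt, reference)
  ks <- .keyString(key$chrom, key$pos, key$ref, key$alt)
  structure(list(keys = ks, freq1 = d$freq1, freq2 = d$freq2),
            class = "frequencyTable")
}

#' Look up population frequencies for normalized variants
#'
#' Variants absent from the table return frequency 0 in both databases:
#' absence from a population resource is evidence of rarity, and novel
#' variants must remain eligible as private.
#'
#' @param chrom,pos,ref,alt normalized variant key columns.
#' @param table a `frequencyTable` from [readFrequencyTable()].
#' @return data.frame with `maf_db1`, `maf_db2` (0 where absent).
#' @export
lookupFrequency <- function(chrom, pos, ref, alt, table) {
  stopifnot(inherits(table, "frequencyTable"))
  i <- match(.keyString(chrom, pos, ref, alt), table$keys)
  data.frame(maf_db1 = ifelse(is.na(i), 0, table$freq1[i]),
             maf_db2 = ifelse(is.na(i), 0, table$freq2[i]))
}
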