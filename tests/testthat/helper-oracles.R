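# Independent oracles the implementation is checked against. These stay
# deliberately naive: enumeration and direct formula evaluation only.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (small-p-values convention, with the
# customary 1e-7 relative tolerance on "not larger than observed").
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pobs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Direct BH step-up evaluation: q_(i) = min_{j>=i} p_(j) * m / j, capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Apply a variant to a contig string, returning the full mutated haplotype.
applyVariant <- function(seqstr, pos, ref, alt) {
  stopifnot(substr(seqstr, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seqstr, 1L, pos - 1L), alt,
         substr(seqstr, pos + nchar(ref), nchar(seqstr)))
}

# Brute-force normalization oracle for simple indels: slide a candidate
# representation across every position of the contig, keep the ones whose
# mutated haplotype matches, and return the leftmost anchored one.
indelOracle <- function(seqstr, pos, ref, alt) {
  target <- applyVariant(seqstr, pos, ref, alt)
  L <- nchar(seqstr)
  k <- nchar(ref) - nchar(alt)
  best <- NULL
  if (k > 0) {          # deletion of k bases, anchored
    for (p in 1:(L - k)) {
      r <- substr(seqstr, p, p + k)
      a <- substr(seqstr, p, p)
      if (applyVariant(seqstr, p, r, a) == target) { best <- list(pos = p, ref = r, alt = a); break }
    }
  } else if (k < 0) {   # insertion of -k bases, anchored
    ins_len <- -k
    for (p in 1:(L - 1L)) {
      anchor <- substr(seqstr, p, p)
      ins <- substr(target, p + 1L, p + ins_len)
      r <- anchor
      a <- paste0(anchor, ins)
      if (applyVariant(seqstr, p, r, a) == target) { best <- list(pos = p, ref = r, alt = a); break }
    }
  }
  best
}

# Translate the spliced CDS of one gene from a gene-model GRanges, used as
# the oracle for nonsense/synonymous calls.
translateCds <- function(gene, gene_model, reference) {
  ex <- gene_model[gene_model$gene == gene]
  ex <- ex[order(ex$exon_rank)]
  strand <- as.character(GenomicRanges::strand(ex))[1]
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  parts <- vapply(seq_along(ex), function(i)
    as.character(Biostrings::subseq(reference[[chrom]],
                                    GenomicRanges::start(ex)[i],
                                    GenomicRanges::end(ex)[i])),
    character(1))
  if (strand == "-")
    parts <- vapply(parts, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1))
  cds <- paste(parts, collapse = "")
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}
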