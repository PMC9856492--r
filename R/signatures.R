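## SBS-96 mutation catalogs, signature refitting by non-negative least
## squares, dominant-signature assignment, exposure clustering and subgroup
## enrichment.

.SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")

#' Canonical SBS-96 category labels
#'
#' The 6 pyrimidine-centric substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G) each in 16 trinucleotide contexts, ordered lexicographically by 5'
#' then 3' flanking base, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ...
#'
#' @return character vector of length 96.
#' @export
sbs96Categories <- function() {
  unlist(lapply(.SBS_CLASSES, function(cl)
    as.vector(t(outer(.BASES, .BASES, function(f, t)
      sprintf("%s[%s]%s", f, cl, t))))))
}

.revcompBase <- function(b) .COMPLEMENT[b]

#' SBS-96 context category of an SNV
#'
#' Purine-reference substitutions are reverse-complemented together with
#' their flanks so the central base is always a pyrimidine; applying the
#' mapping to a variant and to its reverse complement therefore gives the
#' same category. SNVs whose trinucleotide context contains N are returned
#' as NA with a warning.
#'
#' @param chrom,pos,ref,alt SNV key columns (single-base ref and alt).
#' @param reference DNAStringSet.
#' @return integer vector of category indices in 1..96 (ordered as
#'   [sbs96Categories()]), with the category label as names.
#' @export
contextCategory <- function(chrom, pos, ref, alt, reference) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("context categories are defined for SNVs only")
  n <- length(chrom)
  cats <- sbs96Categories()
  out <- integer(n)
  lab <- character(n)
  for (i in seq_len(n)) {
    tri <- .refSlice(reference, chrom[i], pos[i] - 1L, pos[i] + 1L)
    mid <- substr(tri, 2L, 2L)
    if (mid != ref[i])
      stop("reference mismatch at ", chrom[i], ":", pos[i],
           " (expected ", mid, ", got ", ref[i], ")")
    f <- substr(tri, 1L, 1L); t3 <- substr(tri, 3L, 3L)
    r <- ref[i]; a <- alt[i]
    if (any(c(f, r, t3, a) == "N")) {
      out[i] <- NA_integer_; lab[i] <- NA_character_
      warning("variant at ", chrom[i], ":", pos[i],
              " excluded: N in trinucleotide context")
      next
    }
    if (r %in% c("A", "G")) {
      tmp <- f
      f <- .revcompBase(t3); t3 <- .revcompBase(tmp)
      r <- .revcompBase(r); a <- .revcompBase(a)
    }
    label <- sprintf("%s[%s>%s]%s", f, r, a, t3)
    out[i] <- match(label, cats)
    lab[i] <- label
  }
  names(out) <- lab
  out
}

#' Build an SBS-96 mutation catalog from somatic SNVs
#'
#' @param snvs data.frame with `sample_id`, `chrom`, `pos`, `ref`, `alt`;
#'   non-SNV rows are rejected.
#' @param reference DNAStringSet.
#' @param sample_ids catalog rows, in order; samples with no SNVs get a zero
#'   row.
#' @return a [MutationCatalog-class]. Total counts equal the number of SNVs
#'   with a well-defined context.
#' @export
buildCatalog <- function(snvs, reference, sample_ids = NULL) {
  .assertColumns(snvs, c("sample_id", "chrom", "pos", "ref", "alt"), "SNVs")
  if (is.null(sample_ids)) sample_ids <- sort(unique(snvs$sample_id))
  m <- matrix(0L, nrow = length(sample_ids), ncol = 96L,
              dimnames = list(sample_ids, sbs96Categories()))
  if (nrow(snvs)) {
    cat_idx <- contextCategory(snvs$chrom, snvs$pos, snvs$ref, snvs$alt,
                               reference)
    ok <- !is.na(cat_idx)
    tab <- table(factor(snvs$sample_id[ok], levels = sample_ids),
                 factor(cat_idx[ok], levels = 1:96))
    m <- matrix(as.integer(tab), nrow = length(sample_ids),
                dimnames = list(sample_ids, sbs96Categories()))
  }
  new("MutationCatalog", counts = m)
}

#' Construct a SignatureSet from a 96 x K probability matrix
#'
#' @param probs numeric matrix, 96 rows in [sbs96Categories()] order (row
#'   names optional but, if present, must match), named columns.
#' @return a [SignatureSet-class].
#' @export
SignatureSet <- function(probs) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs))) rownames(probs) <- sbs96Categories()
  new("SignatureSet", probs = probs)
}

#' Read / write a signature probability matrix TSV
#'
#' The TSV has a `category` column with the 96 SBS labels and one column per
#' signature.
#' @param path file path.
#' @return [readSignatureMatrix()] returns a [SignatureSet-class].
#' @export
readSignatureMatrix <- function(path) {
  d <- .readTsv(path)
  if (names(d)[1] != "category") stop("first column must be 'category'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$category
  m <- m[match(sbs96Categories(), rownames(m)), , drop = FALSE]
  SignatureSet(m)
}

#' @rdname readSignatureMatrix
#' @param signatures a [SignatureSet-class] to write.
#' @export
writeSignatureMatrix <- function(signatures, path) {
  p <- signatureProbs(signatures)
  .writeTsv(data.frame(category = rownames(p), p, check.names = FALSE), path)
}

## argmax over named weights; exact ties go to the lexicographically
## smallest signature id
.dominantOf <- function(w) {
  top <- names(w)[w == max(w)]
  sort(top)[1L]
}

#' Refit per-sample signature exposures by non-negative least squares
#'
#' Each catalog row is normalized to a frequency vector and decomposed over
#' the signature columns by NNLS; the non-negative solution is renormalized
#' to sum to 1. The reconstruction cosine compares the observed row with its
#' fitted reconstruction (cosine similarity is scale-free, so counts and
#' frequencies give the same value); it is 1 exactly when the catalog row
#' lies in the non-negative span of the signatures. All-zero rows yield NA
#' weights and are flagged.
#'
#' @param catalog a [MutationCatalog-class].
#' @param signatures a [SignatureSet-class].
#' @return an [ExposureSet-class]; dominant ties break towards the
#'   lexicographically smallest signature id.
#' @export
fitExposures <- function(catalog, signatures) {
  m <- catalogCounts(catalog)
  S <- signatureProbs(signatures)
  K <- ncol(S)
  w <- matrix(NA_real_, nrow(m), K, dimnames = list(rownames(m), colnames(S)))
  cosine <- numeric(nrow(m))
  dominant <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    row <- as.numeric(m[i, ])
    tot <- sum(row)
    if (tot == 0) {
      cosine[i] <- NA_real_
      dominant[i] <- NA_character_
      next
    }
    fit <- pracma::lsqnonneg(S, row / tot)
    x <- fit$x
    if (sum(x) == 0) x <- rep(1 / K, K) else x <- x / sum(x)
    w[i, ] <- x
    recon <- as.numeric(S %*% x)
    cosine[i] <- .cosine(row, recon)
    dominant[i] <- .dominantOf(stats::setNames(x, colnames(S)))
  }
  new("ExposureSet", weights = w, cosine = cosine, dominant = dominant)
}

#' Dominant-signature table for a cohort
#'
#' @param exposures an [ExposureSet-class].
#' @return list with `per_sample` (sample_id, dominant, weight) and
#'   `dominance` (signature, n_dominant, n_samples, percent with one
#'   decimal); flagged (all-zero) samples are excluded from the denominator.
#' @export
assignDominant <- function(exposures) {
  w <- exposureWeights(exposures)
  dom <- dominantSignature(exposures)
  ok <- !is.na(dom)
  per_sample <- data.frame(sample_id = rownames(w)[ok],
                           dominant = dom[ok],
                           weight = vapply(which(ok), function(i)
                             w[i, dom[i]], numeric(1)),
                           stringsAsFactors = FALSE)
  counts <- table(factor(dom[ok], levels = colnames(w)))
  dominance <- data.frame(signature = names(counts),
                          n_dominant = as.integer(counts),
                          n_samples = sum(ok),
                          percent = carrierPercent(as.integer(counts), sum(ok)),
                          stringsAsFactors = FALSE)
  list(per_sample = per_sample, dominance = dominance)
}

#' Cluster samples on their exposure vectors
#'
#' Centroid-based (k-means) clustering of the exposure weight vectors with a
#' fixed seed and many restarts, so the assignment is deterministic given
#' the seed. Flagged samples (NA exposures) are dropped.
#'
#' @param exposures an [ExposureSet-class].
#' @param k number of clusters (>= 2; typically swept over 3, 4, 5).
#' @param seed integer RNG seed.
#' @param nstart k-means restarts (default 25).
#' @return named integer vector of cluster labels in 1..k.
#' @export
clusterExposures <- function(exposures, k, seed = 1L, nstart = 25L) {
  w <- exposureWeights(exposures)
  w <- w[!apply(is.na(w), 1L, any), , drop = FALSE]
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(w)) stop("k (", k, ") exceeds the number of samples (",
                        nrow(w), ")")
  if (k == nrow(w)) {  # exact solution: every sample is its own centroid
    labels <- seq_len(nrow(w))
    names(labels) <- rownames(w)
    return(labels)
  }
  labels <- local({
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    km <- suppressWarnings(stats::kmeans(w, centers = k, nstart = nstart,
                                         iter.max = 100L))
    km$cluster
  })
  names(labels) <- rownames(w)
  labels
}

#' 2x2 subgroup enrichment with a Fisher exact test
#'
#' Cross-tabulates two per-sample logical flags (rows = `flagA`, columns =
#' `flagB`) and tests association with a two-sided Fisher exact test.
#' Samples with NA in either flag are excluded and counted.
#'
#' @param flagA,flagB logical vectors of equal length (NA = unknown).
#' @return list with the 2x2 `table`, `p` (two-sided Fisher), and
#'   `n_excluded`.
#' @export
enrichment2x2 <- function(flagA, flagB) {
  stopifnot(length(flagA) == length(flagB))
  ok <- !is.na(flagA) & !is.na(flagB)
  tab <- table(factor(flagA[ok], levels = c(TRUE, FALSE)),
               factor(flagB[ok], levels = c(TRUE, FALSE)))
  if (sum(tab) == 0L) stop("empty contingency table")
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("contingency table has a zero margin")
  list(table = tab, p = fisherExact(tab), n_excluded = sum(!ok))
}
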