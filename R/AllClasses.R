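#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## Mutation catalogs and signatures
## ---------------------------------------------------------------------------

#' MutationCatalog: per-sample SBS-96 mutation counts
#'
#' A samples x 96 integer count matrix over the pyrimidine-centric
#' single-base-substitution categories (6 substitution classes C>A, C>G, C>T,
#' T>A, T>C, T>G, each in 16 trinucleotide contexts ordered lexicographically
#' by 5' then 3' flanking base). Column names are fixed to
#' [sbs96Categories()].
#'
#' @slot counts samples x 96 non-negative integer matrix; rownames are sample
#'   ids, colnames the 96 category labels.
#' @export
setClass("MutationCatalog", representation(counts = "matrix"))

setValidity("MutationCatalog", function(object) {
  m <- object@counts
  if (ncol(m) != 96L) return("catalog must have exactly 96 columns")
  if (!identical(colnames(m), sbs96Categories()))
    return("catalog columns must be the canonical SBS-96 categories in order")
  if (is.null(rownames(m))) return("catalog rows must be named by sample id")
  if (any(m < 0) || any(m != round(m))) return("counts must be non-negative integers")
  TRUE
})

#' SignatureSet: a 96 x K signature probability matrix
#'
#' Each column is a probability distribution over the 96 SBS categories
#' (columns sum to 1), as in the COSMIC SBS catalogue.
#'
#' @slot probs 96 x K numeric matrix; rownames are the category labels,
#'   colnames the signature ids.
#' @export
setClass("SignatureSet", representation(probs = "matrix"))

setValidity("SignatureSet", function(object) {
  p <- object@probs
  if (nrow(p) != 96L) return("signature matrix must have 96 rows")
  if (!identical(rownames(p), sbs96Categories()))
    return("signature rows must be the canonical SBS-96 categories in order")
  if (is.null(colnames(p))) return("signatures must be named")
  if (any(p < 0)) return("signature probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-8)) return("each signature column must sum to 1")
  TRUE
})

#' ExposureSet: per-sample signature exposures from refitting
#'
#' Non-negative per-sample weights over the signatures of a [SignatureSet],
#' renormalized to sum to 1, with the cosine similarity between each observed
#' catalog row and its reconstruction, and the dominant (argmax) signature.
#' Samples whose catalog row was all zero carry NA weights and are flagged.
#'
#' @slot weights samples x K numeric matrix of exposures (rows sum to 1, or
#'   all NA for flagged samples).
#' @slot cosine numeric vector, reconstruction cosine per sample.
#' @slot dominant character vector, dominant signature id per sample (ties
#'   broken towards the lexicographically smallest id).
#' @export
setClass("ExposureSet", representation(weights = "matrix",
                                       cosine = "numeric",
                                       dominant = "character"))

setValidity("ExposureSet", function(object) {
  w <- object@weights
  if (is.null(rownames(w)) || is.null(colnames(w)))
    return("exposure weights must have sample and signature names")
  if (length(object@cosine) != nrow(w) || length(object@dominant) != nrow(w))
    return("cosine and dominant must have one entry per sample")
  ok <- !apply(is.na(w), 1L, any)
  if (any(w[ok, , drop = FALSE] < -1e-12))
    return("exposure weights must be non-negative")
  if (any(abs(rowSums(w[ok, , drop = FALSE]) - 1) > 1e-8))
    return("exposure weights must sum to 1 per sample")
  TRUE
})

## ---------------------------------------------------------------------------
## Variant-level call sets
## ---------------------------------------------------------------------------

#' PrivateCallSet: six-criterion private-variant calls
#'
#' One row per (patient, variant) with the six per-criterion logical flags
#' and the overall verdict. The validity method enforces the defining
#' invariant: `is_private` is exactly the conjunction of the six flags.
#'
#' @slot calls a [S4Vectors::DataFrame] with at least the columns
#'   `patient_id`, `gene`, `c1_consequence`, `c2_het`, `c3_rare`,
#'   `c4_singleton`, `c5_mappable`, `c6_unique`, `is_private`.
#' @export
setClass("PrivateCallSet", representation(calls = "DataFrame"))

.PRIVATE_FLAGS <- c("c1_consequence", "c2_het", "c3_rare",
                    "c4_singleton", "c5_mappable", "c6_unique")

setValidity("PrivateCallSet", function(object) {
  d <- object@calls
  need <- c("patient_id", "gene", .PRIVATE_FLAGS, "is_private")
  missing <- setdiff(need, colnames(d))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  conj <- Reduce(`&`, lapply(.PRIVATE_FLAGS, function(f) d[[f]]))
  if (!identical(as.logical(d$is_private), as.logical(conj)))
    return("is_private must equal the conjunction of the six criterion flags")
  TRUE
})

#' DoubleHitSet: germline-heterozygous variants homozygous in the tumor
#'
#' One row per (patient, variant) double-hit event. Construction asserts that
#' every underlying germline call is heterozygous and that at least one
#' evidence clause fired.
#'
#' @slot events a [S4Vectors::DataFrame] with columns `patient_id`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `germline_zygosity`, `tumor_vaf`,
#'   `tumor_depth`, `evidence` (comma-separated tags from
#'   `genotype_homozygous`, `vaf_threshold`, `loh_overlap`).
#' @export
setClass("DoubleHitSet", representation(events = "DataFrame"))

setValidity("DoubleHitSet", function(object) {
  d <- object@events
  need <- c("patient_id", "gene", "chrom", "pos", "ref", "alt",
            "germline_zygosity", "tumor_vaf", "tumor_depth", "evidence")
  missing <- setdiff(need, colnames(d))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  if (nrow(d) && any(d$germline_zygosity != "het"))
    return("every double-hit event must arise from a heterozygous germline call")
  if (nrow(d) && any(!nzchar(d$evidence)))
    return("every event must carry at least one evidence tag")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic bundles
## ---------------------------------------------------------------------------

#' SyntheticBundle: an on-disk synthetic cohort with planted truth
#'
#' Returned by [simulateCohort()]; holds the output directory, the paths of
#' every generated file, the generating configuration, and the in-memory
#' truth tables.
#'
#' @slot dir output directory.
#' @slot paths named list of file paths.
#' @slot config the [simulationConfig()] list used.
#' @slot truth named list of truth data frames.
#' @export
setClass("SyntheticBundle", representation(dir = "character",
                                           paths = "list",
                                           config = "list",
                                           truth = "list"))

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @describeIn MutationCatalog-class the counts matrix
#' @param object,x an object of the documented class
#' @export
setGeneric("catalogCounts", function(x) standardGeneric("catalogCounts"))
#' @export
setMethod("catalogCounts", "MutationCatalog", function(x) x@counts)

#' @export
setGeneric("signatureProbs", function(x) standardGeneric("signatureProbs"))
#' @export
setMethod("signatureProbs", "SignatureSet", function(x) x@probs)

#' @export
setGeneric("exposureWeights", function(x) standardGeneric("exposureWeights"))
#' @export
setMethod("exposureWeights", "ExposureSet", function(x) x@weights)

#' @export
setGeneric("reconstructionCosine", function(x) standardGeneric("reconstructionCosine"))
#' @export
setMethod("reconstructionCosine", "ExposureSet", function(x) x@cosine)

#' @export
setGeneric("dominantSignature", function(x) standardGeneric("dominantSignature"))
#' @export
setMethod("dominantSignature", "ExposureSet", function(x) x@dominant)

#' @export
setGeneric("privateCalls", function(x) standardGeneric("privateCalls"))
#' @export
setMethod("privateCalls", "PrivateCallSet", function(x) x@calls)

#' @export
setGeneric("doubleHitEvents", function(x) standardGeneric("doubleHitEvents"))
#' @export
setMethod("doubleHitEvents", "DoubleHitSet", function(x) x@events)

#' @export
setGeneric("bundleDir", function(x) standardGeneric("bundleDir"))
#' @export
setMethod("bundleDir", "SyntheticBundle", function(x) x@dir)

#' @export
setGeneric("bundlePaths", function(x) standardGeneric("bundlePaths"))
#' @export
setMethod("bundlePaths", "SyntheticBundle", function(x) x@paths)

#' @export
setGeneric("bundleTruth", function(x) standardGeneric("bundleTruth"))
#' @export
setMethod("bundleTruth", "SyntheticBundle", function(x) x@truth)

#' @export
setGeneric("bundleConfig", function(x) standardGeneric("bundleConfig"))
#' @export
setMethod("bundleConfig", "SyntheticBundle", function(x) x@config)

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog with", nrow(object@counts), "samples,",
      sum(object@counts), "mutations\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet with", ncol(object@probs), "signatures:",
      paste(colnames(object@probs), collapse = ", "), "\n")
})

setMethod("show", "ExposureSet", function(object) {
  cat("ExposureSet for", nrow(object@weights), "samples over",
      ncol(object@weights), "signatures\n")
  tab <- table(object@dominant)
  cat("dominant:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PrivateCallSet", function(object) {
  d <- object@calls
  cat("PrivateCallSet:", nrow(d), "candidate calls,",
      sum(d$is_private), "private, in",
      length(unique(d$patient_id[d$is_private])), "patients\n")
})

setMethod("show", "DoubleHitSet", function(object) {
  d <- object@events
  cat("DoubleHitSet:", nrow(d), "events in",
      length(unique(d$patient_id)), "patients\n")
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle in", object@dir, "\n")
  cat(" ", object@config$n_patients, "patients,",
      object@config$n_genes, "genes,",
      object@config$n_contigs, "contigs\n")
})
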