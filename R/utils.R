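#' Percentage rounded to one decimal
#'
#' Cohort tables report percentages to one decimal place, rounded half away
#' from zero (so 2.85 prints as 2.9, not 2.8). This is the single primitive
#' behind every "n of N (x%)" figure the package emits.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @return `100 * numerator / denominator`, rounded half away from zero to one
#'   decimal.
#' @examples
#' carrierPercent(8, 284)   # 2.8
#' carrierPercent(53, 284)  # 18.7
#' @export
carrierPercent <- function(numerator, denominator) {
  if (any(denominator == 0)) stop("denominator must be > 0")
  if (any(numerator < 0) || any(denominator < 0)) stop("counts must be >= 0")
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

## shared string key for a normalized variant; used for all joins/lookups
.keyString <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.assertColumns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

## cosine similarity of two non-negative vectors; 0 if either is all-zero
.cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

## deterministic TSV writer used for all stage outputs
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
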