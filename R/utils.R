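#' Round half away from zero
#'
#' Standard `round()` in R rounds half to even; printed percentages in
#' tabular reports conventionally round half away from zero, so 9.65 becomes
#' 9.7 rather than 9.6. Used by all percentage-reporting helpers.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
roundHalfAway <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage coverage of a numerator over a denominator
#'
#' Computes `100 * numerator / denominator` rounded half away from zero to
#' the requested number of decimals, the convention used for coverage
#' figures such as the fraction of the protein-coding retinal transcriptome
#' quantified at the protein level.
#'
#' @param numerator non-negative count.
#' @param denominator positive count.
#' @param decimals decimal places to keep (default 1).
#' @return a single number, the rounded percentage.
#' @examples
#' coverageFraction(1237, 12758)      # 9.7
#' coverageFraction(1237, 1446, 0)    # 86
#' @export
coverageFraction <- function(numerator, denominator, decimals = 1) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            length(numerator) == 1, length(denominator) == 1)
  if (denominator == 0) {
    stop("coverageFraction: denominator must be non-zero")
  }
  roundHalfAway(100 * numerator / denominator, decimals)
}

# Read a TSV with a mandatory header; returns a data.frame with character
# columns left unconverted. Shared by all tabular readers.
.readTsv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Require columns in a freshly read table, reporting all that are missing.
.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Deterministic sub-stream seeding: each simulated table draws from its own
# stream derived from the master seed, so adding a table to the study never
# perturbs the others. Offsets are fixed per table kind.
.withSubstream <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((abs(seed) %% 1048576L) * 1021L + offset)
  expr
}
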