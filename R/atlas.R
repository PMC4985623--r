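#' Read a multi-dataset expression atlas
#'
#' The atlas collates normalized expression values (FPKM/RPKM, treated as
#' one unit and pooled without rescaling) for one gene per dataset per row.
#'
#' @param path TSV with header columns `gene`, `dataset`, `value`.
#' @return data.frame of validated records.
#' @export
readAtlas <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("gene", "dataset", "value"),
                  paste0("atlas file ", path))
  df$value <- as.numeric(df$value)
  bad <- which(is.na(df$value) | df$value < 0)
  if (length(bad) > 0) {
    stop("atlas values must be non-negative numbers; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df[, c("gene", "dataset", "value")]
}

#' Call genes expressed at an abundance cutoff
#'
#' A gene is deemed expressed when its maximum value over datasets is at or
#' above `cutoff` (inclusive, so a value of exactly 0.5 passes at the
#' default). Genes absent from all datasets are simply not in the output.
#'
#' @param records data.frame from [readAtlas()] (columns `gene`,
#'   `dataset`, `value`).
#' @param cutoff positive expression cutoff in FPKM/RPKM (default 0.5).
#' @return data.frame with columns `gene`, `maxValue`, `expressed`,
#'   sorted by gene.
#' @export
callExpressed <- function(records, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  .requireColumns(records, c("gene", "value"), "atlas records")
  if (nrow(records) == 0) {
    return(data.frame(gene = character(0), maxValue = numeric(0),
                      expressed = logical(0), stringsAsFactors = FALSE))
  }
  mx <- tapply(records$value, records$gene, max)
  res <- data.frame(gene = names(mx), maxValue = as.numeric(mx),
                    expressed = as.numeric(mx) >= cutoff,
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Restrict atlas genes to protein-coding biotypes
#'
#' @param genes data.frame from [callExpressed()].
#' @param biotypes data.frame with columns `gene`, `biotype`, or a named
#'   character vector gene -> biotype.
#' @param unknown policy for genes missing from the biotype table:
#'   `"drop"` (default; excluded with a warning) or `"keep"`.
#' @return the subset of `genes` whose biotype is `protein_coding`, with a
#'   `proteinCoding` column added (all TRUE under `"drop"`).
#' @export
filterProteinCoding <- function(genes, biotypes, unknown = c("drop", "keep")) {
  unknown <- match.arg(unknown)
  if (is.data.frame(biotypes)) {
    .requireColumns(biotypes, c("gene", "biotype"), "biotype table")
    bt <- stats::setNames(as.character(biotypes$biotype),
                          as.character(biotypes$gene))
  } else {
    bt <- biotypes
  }
  status <- bt[genes$gene]
  nMissing <- sum(is.na(status))
  if (nMissing > 0) {
    warning(nMissing, " gene(s) missing from the biotype table (policy: ",
            unknown, ")")
  }
  keep <- if (unknown == "drop") {
    !is.na(status) & status == "protein_coding"
  } else {
    is.na(status) | status == "protein_coding"
  }
  res <- genes[keep, , drop = FALSE]
  res$proteinCoding <- rep(TRUE, nrow(res))
  rownames(res) <- NULL
  res
}
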