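#' Thresholds for inverse-pair discovery
#'
#' miRNA and protein fold-changes (percent of wild type) inside the band
#' are treated as unchanged; the defaults require alterations in excess of
#' +/- 25% (below 75% or above 125% of wild-type levels) and raw
#' significance p < 0.05.
#'
#' @param alpha significance level for the protein change (default 0.05).
#' @param mirnaBand length-2 numeric, percent-of-wt band treated as
#'   unchanged for miRNAs (default c(75, 125)).
#' @param proteinBand same for protein folds (default c(75, 125)).
#' @return a validated list of thresholds.
#' @export
pairThresholds <- function(alpha = 0.05, mirnaBand = c(75, 125),
                           proteinBand = c(75, 125)) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1)
  for (b in list(mirnaBand, proteinBand)) {
    if (length(b) != 2 || b[1] > 100 || b[2] < 100) {
      stop("fold bands must be length 2 and straddle 100%")
    }
  }
  list(alpha = alpha, mirnaBand = sort(mirnaBand),
       proteinBand = sort(proteinBand))
}

#' Read a miRNA fold-change table
#'
#' @param path TSV with columns `mirna`, `fold_retina_percent` and
#'   optionally `fold_photoreceptor_percent` (percent of wild type).
#' @return validated data.frame.
#' @export
readMirnaChanges <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("mirna", "fold_retina_percent"),
                  paste0("miRNA changes file ", path))
  df$fold_retina_percent <- as.numeric(df$fold_retina_percent)
  if (any(is.na(df$fold_retina_percent) | df$fold_retina_percent <= 0)) {
    stop("fold_retina_percent must be positive")
  }
  if (!"fold_photoreceptor_percent" %in% names(df)) {
    df$fold_photoreceptor_percent <- NA_real_
  }
  df
}

#' Discover candidate miRNA-target pairs under the inverse-expression rule
#'
#' A pair (miRNA, gene) is emitted iff the gene is an in-silico candidate
#' of the miRNA, the miRNA's retinal fold lies outside its unchanged band,
#' and the gene's protein fold is significant (p < alpha) and outside its
#' band in the opposite direction in at least one fraction. Every
#' qualifying fraction is listed in `fractions_supporting`; a fraction
#' where the protein moved significantly in the same direction as the
#' miRNA (i.e. against the pair) does not veto the pair but is flagged in
#' `conflicting_fraction`. The retina fold column drives the band test;
#' the photoreceptor fold, when present, is carried as annotation only.
#' Only representative records (see [mapProteinsToGenes()]) are used when
#' a `representative` column is present.
#'
#' @param mirnaChanges data.frame from [readMirnaChanges()].
#' @param de gene-mapped results from [mapProteinsToGenes()].
#' @param candidates named list (miRNA -> gene character vector) from
#'   [candidatesPerMirna()].
#' @param thresholds list from [pairThresholds()].
#' @return data.frame with one row per pair: `mirna`, `gene`, `direction`
#'   (`mirna_up_protein_down` or `mirna_down_protein_up`),
#'   `fractions_supporting` (comma-separated), `conflicting_fraction`,
#'   `protein_fold_percent`, `protein_p` (from the best-supporting
#'   fraction, smallest p), `mirna_fold_percent`.
#' @export
inversePairs <- function(mirnaChanges, de, candidates,
                         thresholds = pairThresholds()) {
  emptyPairs <- data.frame(
    mirna = character(0), gene = character(0), direction = character(0),
    fractions_supporting = character(0), conflicting_fraction = character(0),
    protein_fold_percent = numeric(0), protein_p = numeric(0),
    mirna_fold_percent = numeric(0), stringsAsFactors = FALSE)
  if (length(candidates) == 0) {
    return(emptyPairs)
  }
  if ("representative" %in% names(de)) {
    de <- de[de$representative, , drop = FALSE]
  }
  out <- list()
  for (m in names(candidates)) {
    row <- match(m, mirnaChanges$mirna)
    if (is.na(row)) {
      warning("miRNA absent from the fold-change table, skipped: ", m)
      next
    }
    mf <- mirnaChanges$fold_retina_percent[row]
    if (mf >= thresholds$mirnaBand[1] && mf <= thresholds$mirnaBand[2]) {
      next  # miRNA unchanged
    }
    mirnaUp <- mf > thresholds$mirnaBand[2]
    for (g in candidates[[m]]) {
      recs <- de[!is.na(de$gene) & de$gene == g, , drop = FALSE]
      if (nrow(recs) == 0) next
      sig <- !is.na(recs$p_value) & recs$p_value < thresholds$alpha &
        !is.na(recs$fold_percent)
      protUp <- recs$fold_percent > thresholds$proteinBand[2]
      protDown <- recs$fold_percent < thresholds$proteinBand[1]
      supporting <- sig & (if (mirnaUp) protDown else protUp)
      conflicting <- sig & (if (mirnaUp) protUp else protDown)
      if (!any(supporting)) next
      si <- which(supporting)
      best <- si[order(recs$p_value[si])][1]
      out[[length(out) + 1L]] <- data.frame(
        mirna = m, gene = g,
        direction = if (mirnaUp) "mirna_up_protein_down" else
          "mirna_down_protein_up",
        fractions_supporting = paste(sort(recs$fraction[supporting]),
                                     collapse = ","),
        conflicting_fraction = paste(sort(recs$fraction[conflicting]),
                                     collapse = ","),
        protein_fold_percent = recs$fold_percent[best],
        protein_p = recs$p_value[best],
        mirna_fold_percent = mf,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(emptyPairs)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Co-targeting matrix of discovered pairs
#'
#' @param pairs data.frame from [inversePairs()].
#' @return symmetric integer matrix, miRNA x miRNA; the diagonal holds
#'   per-miRNA target counts, off-diagonals the number of shared targets.
#' @export
sharedTargets <- function(pairs) {
  mirnas <- sort(unique(pairs$mirna))
  sets <- lapply(split(pairs$gene, pairs$mirna), unique)
  m <- matrix(0L, length(mirnas), length(mirnas),
              dimnames = list(mirnas, mirnas))
  for (i in seq_along(mirnas)) {
    for (j in seq_along(mirnas)) {
      m[i, j] <- length(intersect(sets[[mirnas[i]]], sets[[mirnas[j]]]))
    }
  }
  m
}
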