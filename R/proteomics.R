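#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
NULL

#' Construct a ProteomicsExperiment from a long quantification table
#'
#' @param quant data.frame with columns `protein_id`, `fraction` (whole or
#'   membrane), `group` (mutant or wt), `replicate`, `abundance`.
#' @return a [ProteomicsExperiment-class].
#' @export
proteomicsExperiment <- function(quant) {
  .requireColumns(quant, c("protein_id", "fraction", "group",
                           "replicate", "abundance"),
                  "protein quantification table")
  quant$abundance <- as.numeric(quant$abundance)
  if (any(is.na(quant$abundance) & !is.na(quant$protein_id)) ||
      any(quant$abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative numbers")
  }
  run <- paste(quant$fraction, quant$group, quant$replicate, sep = ".")
  runs <- unique(data.frame(run = run, fraction = quant$fraction,
                            group = quant$group,
                            replicate = quant$replicate,
                            stringsAsFactors = FALSE))
  runs <- runs[order(runs$fraction, runs$group, runs$replicate), ,
               drop = FALSE]
  proteins <- sort(unique(quant$protein_id))
  m <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(runs),
              dimnames = list(proteins, runs$run))
  ij <- cbind(match(quant$protein_id, proteins), match(run, runs$run))
  if (anyDuplicated(ij)) {
    stop("duplicate (protein, fraction, group, replicate) entries")
  }
  m[ij] <- quant$abundance
  cd <- S4Vectors::DataFrame(fraction = runs$fraction, group = runs$group,
                             replicate = runs$replicate,
                             row.names = runs$run)
  methods::new("ProteomicsExperiment",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(abundance = m), colData = cd))
}

#' Read a protein quantification TSV
#'
#' @param path TSV with header columns `protein_id`, `fraction`, `group`,
#'   `replicate`, `abundance`.
#' @return a [ProteomicsExperiment-class].
#' @export
readProteinQuant <- function(path) {
  df <- .readTsv(path)
  proteomicsExperiment(df)
}

# Pooled-variance two-group comparison; for two groups the one-way ANOVA
# F-test and the two-sided pooled t-test coincide. Returns NA when the
# pooled within-group variance is zero (test undefined) -- never 0 or 1.
.pooledP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tval), df = n1 + n2 - 2)
}

#' @describeIn differentialAbundance Per-protein, per-fraction fold and
#'   p-value. The fold is expressed as percent of wild type
#'   (`100 * mean(mutant) / mean(wt)`) alongside its log2; significance is
#'   a one-way two-group analysis of variance on abundances (equivalent to
#'   the two-sided pooled-variance t-test), computed independently per
#'   fraction with no cross-fraction pooling and no multiple-testing
#'   correction (downstream filters use raw p < 0.05; BH q-values appear
#'   only in the over-representation stage). With `transform = "log2"` the
#'   test runs on log2 abundances (a pseudocount of half the smallest
#'   positive value guards zeros); the fold is always computed from raw
#'   means. Proteins with fewer than 2 replicates in a group are skipped
#'   with a warning; a zero wild-type mean yields a missing fold, flagged
#'   in `note`; zero within-group variance in both groups yields a missing
#'   p-value, never 0 or 1.
#' @param transform `"none"` (default) to test raw abundances, `"log2"`
#'   to test log2-transformed abundances.
#' @export
setMethod("differentialAbundance", "ProteomicsExperiment",
          function(object, transform = c("none", "log2")) {
  transform <- match.arg(transform)
  m <- SummarizedExperiment::assay(object, "abundance")
  cd <- SummarizedExperiment::colData(object)
  out <- list()
  nSkipped <- 0L
  for (fr in unique(cd$fraction)) {
    mi <- which(cd$fraction == fr & cd$group == "mutant")
    wi <- which(cd$fraction == fr & cd$group == "wt")
    for (p in rownames(m)) {
      a <- m[p, mi]; a <- a[!is.na(a)]
      b <- m[p, wi]; b <- b[!is.na(b)]
      if (length(a) == 0 && length(b) == 0) next
      if (length(a) < 2 || length(b) < 2) {
        nSkipped <- nSkipped + 1L
        next
      }
      note <- ""
      if (mean(b) > 0) {
        foldPct <- 100 * mean(a) / mean(b)
        log2Fold <- log2(mean(a) / mean(b))
      } else {
        foldPct <- NA_real_
        log2Fold <- NA_real_
        note <- "zero_wt_mean"
      }
      if (transform == "log2") {
        pos <- c(a, b)[c(a, b) > 0]
        eps <- if (length(pos) > 0) min(pos) / 2 else 1
        pv <- .pooledP(log2(a + eps), log2(b + eps))
      } else {
        pv <- .pooledP(a, b)
      }
      out[[length(out) + 1L]] <- data.frame(
        protein_id = p, gene = NA_character_, fraction = fr,
        fold_percent = foldPct, log2_fold = log2Fold, p_value = pv,
        note = note, stringsAsFactors = FALSE)
    }
  }
  if (nSkipped > 0) {
    warning(nSkipped, " protein/fraction combination(s) skipped: ",
            "fewer than 2 replicates per group")
  }
  if (length(out) == 0) {
    return(data.frame(protein_id = character(0), gene = character(0),
                      fraction = character(0), fold_percent = numeric(0),
                      log2_fold = numeric(0), p_value = numeric(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
})

#' Map differential results from protein to gene identifiers
#'
#' Many-to-one protein-to-gene mapping is permitted. Within each (gene,
#' fraction) one record is marked `representative` (default policy: the
#' entry with the smallest p-value; missing p sorts last, ties broken by
#' protein id) for downstream per-gene analyses. Unmapped proteins are
#' retained with a missing gene and counted in the `unmapped` attribute.
#'
#' @param results data.frame from [differentialAbundance()].
#' @param mapping data.frame with columns `protein_id`, `gene`.
#' @return `results` with `gene` filled and a logical `representative`
#'   column; `attr(, "unmapped")` carries the number of unmapped proteins.
#' @export
mapProteinsToGenes <- function(results, mapping) {
  .requireColumns(mapping, c("protein_id", "gene"), "protein-gene mapping")
  res <- results
  res$gene <- mapping$gene[match(res$protein_id, mapping$protein_id)]
  res$representative <- FALSE
  mappedIdx <- which(!is.na(res$gene))
  if (length(mappedIdx) > 0) {
    key <- paste(res$gene[mappedIdx], res$fraction[mappedIdx], sep = "\r")
    for (ii in split(mappedIdx, key)) {
      p <- res$p_value[ii]
      ord <- order(is.na(p), p, res$protein_id[ii])
      res$representative[ii[ord[1]]] <- TRUE
    }
  }
  attr(res, "unmapped") <- length(unique(res$protein_id[is.na(res$gene)]))
  res
}

#' Fraction of genes annotated with a term
#'
#' Computes `100 * |genes carrying term| / |genes present in annotation|`
#' to one decimal (half away from zero), e.g. the share of membrane-
#' annotated genes among those found in a Gene Ontology annotation table.
#' Genes absent from the annotation are excluded from the denominator.
#'
#' @param genes character vector of gene identifiers.
#' @param annotation data.frame with columns `gene` and `terms`
#'   (pipe-separated term list), or a named character vector.
#' @param term the term to count, matched exactly against the split list.
#' @return a single percentage.
#' @export
termMembershipFraction <- function(genes, annotation, term) {
  if (is.data.frame(annotation)) {
    .requireColumns(annotation, c("gene", "terms"), "annotation table")
    ann <- stats::setNames(as.character(annotation$terms),
                           as.character(annotation$gene))
  } else {
    ann <- annotation
  }
  genes <- unique(genes)
  present <- genes[genes %in% names(ann)]
  if (length(present) == 0) {
    stop("no queried gene is present in the annotation table")
  }
  has <- vapply(strsplit(ann[present], "|", fixed = TRUE),
                function(tt) term %in% tt, logical(1))
  roundHalfAway(100 * sum(has) / length(present), 1)
}

#' Volcano-plot coordinates with fixed clamping
#'
#' Maps each result to (log2 fold, -log10 p) with the horizontal axis
#' clamped to [-6, 6] and the vertical axis to [0, 4]; entries outside the
#' limits are set to the limiting values. Rows lacking a fold or p-value
#' are dropped.
#'
#' @param results data.frame from [differentialAbundance()].
#' @return data.frame with columns `protein_id`, `fraction`, `x`, `y`.
#' @export
volcanoPoints <- function(results) {
  keep <- !is.na(results$log2_fold) & !is.na(results$p_value)
  r <- results[keep, , drop = FALSE]
  data.frame(
    protein_id = r$protein_id,
    fraction = r$fraction,
    x = pmin(6, pmax(-6, r$log2_fold)),
    y = pmin(4, pmax(0, -log10(r$p_value))),
    stringsAsFactors = FALSE)
}
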