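#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `set_id`, `description`,
#' then members. The description field doubles as the source-database tag
#' (`reactome`, `wikipathways`, `mousecyc`, anything else is `other`);
#' matching is case-insensitive on the leading token of the description.
#'
#' @param path GMT file.
#' @return named list of gene sets; each element is a character vector of
#'   members with attributes `source` and `description`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line ", i, ": need id, description, >=1 member")
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop("malformed GMT line ", i, ": empty member list")
    }
    src <- tolower(strsplit(f[2], "[^A-Za-z]")[[1]][1])
    if (!src %in% c("reactome", "wikipathways", "mousecyc")) src <- "other"
    attr(members, "source") <- src
    attr(members, "description") <- f[2]
    sets[[f[1]]] <- members
  }
  sets
}

#' Select up- and down-regulated gene sets from differential results
#'
#' Up-regulation means a fold strictly above `upFold` (mutant/wt ratio;
#' a fold of exactly 2.0 is excluded) with p < alpha; down-regulation a
#' fold strictly below `downFold` with p < alpha. Representative records
#' are used when flagged; a gene regulated in any fraction qualifies, and
#' the two sets are made disjoint (a gene up in one fraction and down in
#' the other is dropped from both with a warning).
#'
#' @param de data.frame from [differentialAbundance()] /
#'   [mapProteinsToGenes()].
#' @param alpha significance level (default 0.05).
#' @param upFold ratio above which a protein counts as up (default 2.0).
#' @param downFold ratio below which a protein counts as down (default 0.5).
#' @param by identifier to collect: `"gene"` (default; unmapped rows are
#'   ignored) or `"protein_id"`.
#' @return list with character vectors `up` and `down`.
#' @export
selectRegulated <- function(de, alpha = 0.05, upFold = 2.0, downFold = 0.5,
                            by = c("gene", "protein_id")) {
  by <- match.arg(by)
  stopifnot(nrow(de) > 0)
  if (by == "gene" && "representative" %in% names(de)) {
    de <- de[de$representative, , drop = FALSE]
  }
  id <- de[[by]]
  ok <- !is.na(id) & !is.na(de$p_value) & !is.na(de$fold_percent) &
    de$p_value < alpha
  ratio <- de$fold_percent / 100
  up <- unique(id[ok & ratio > upFold])
  down <- unique(id[ok & ratio < downFold])
  both <- intersect(up, down)
  if (length(both) > 0) {
    warning(length(both), " identifier(s) regulated in both directions ",
            "across fractions; dropped from both sets")
    up <- setdiff(up, both)
    down <- setdiff(down, both)
  }
  list(up = sort(up), down = sort(down))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of a foreground list
#' relative to a background universe. For each set the effective set is
#' its intersection with the background; the p-value is the upper-tail
#' hypergeometric probability of observing at least the overlap between
#' foreground and effective set when drawing |foreground| genes from the
#' background. Sets whose overlap reaches `minOverlap` are the tested
#' family: Benjamini-Hochberg q-values are computed across that family
#' first, then the `pCut` filter is applied to the report.
#'
#' @param foreground character vector, must be a subset of `background`.
#' @param background character vector, the gene universe.
#' @param sets named list of gene sets (see [readGmt()]).
#' @param minOverlap minimum foreground overlap for a set to be tested
#'   (default 2).
#' @param pCut p-value cutoff for reporting (default 0.05).
#' @return data.frame sorted by p: `set_id`, `source`, `set_size`,
#'   `effective_set_size`, `overlap`, `p_value`, `q_value`,
#'   `neg_log10_p_clamped`, `neg_log10_q_clamped` (both clamped at 3 for
#'   bar-chart rendering).
#' @export
overrepresentation <- function(foreground, background, sets,
                               minOverlap = 2, pCut = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background universe")
  }
  N <- length(background)
  nF <- length(foreground)
  rows <- lapply(names(sets), function(id) {
    eff <- intersect(sets[[id]], background)
    k <- length(intersect(foreground, eff))
    if (k < minOverlap) return(NULL)
    p <- stats::phyper(k - 1, length(eff), N - length(eff), nF,
                       lower.tail = FALSE)
    src <- attr(sets[[id]], "source")
    data.frame(set_id = id,
               source = if (is.null(src)) "other" else src,
               set_size = length(sets[[id]]),
               effective_set_size = length(eff),
               overlap = k, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  empty <- data.frame(set_id = character(0), source = character(0),
                      set_size = integer(0), effective_set_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      q_value = numeric(0), neg_log10_p_clamped = numeric(0),
                      neg_log10_q_clamped = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0) {
    return(empty)
  }
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$p_value < pCut, , drop = FALSE]
  if (nrow(res) == 0) {
    return(empty)
  }
  res$neg_log10_p_clamped <- pmin(3, -log10(res$p_value))
  res$neg_log10_q_clamped <- pmin(3, -log10(res$q_value))
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
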