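#' @importFrom GenomicRanges GRanges seqnames start end mcols mcols<-
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

.REGIONS <- c("five_prime_utr", "cds", "three_prime_utr")

#' Convert a site table to a GRanges of predicted target sites
#'
#' Predicted miRNA target sites live on transcript coordinates, so the
#' returned `GRanges` uses the transcript identifier as its sequence name
#' and 1-based closed intervals (the native IRanges convention, matching
#' the dialect emitted by the prediction tools). Metadata columns carry
#' `mirna`, `gene`, `region`, `tool` and optional `score`.
#'
#' Site lengths outside the 6-30 nt range that target-prediction tools
#' typically report trigger a warning, not rejection: tool-reported blocks
#' can be shorter or longer and the bound is descriptive, not a rule.
#'
#' @param df data.frame with columns `tool`, `mirna`, `gene`, `transcript`,
#'   `region`, `start`, `end` and optionally `score`.
#' @return a `GRanges` of predicted sites.
#' @export
predictedSites <- function(df) {
  .requireColumns(df, c("tool", "mirna", "gene", "transcript",
                        "region", "start", "end"), "predicted sites")
  if (nrow(df) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      mirna = character(0), gene = character(0), region = character(0),
      tool = character(0), score = numeric(0))
    return(gr)
  }
  start <- as.integer(df$start)
  end <- as.integer(df$end)
  bad <- which(is.na(start) | is.na(end) | end < start | start < 1)
  if (length(bad) > 0) {
    stop("invalid site coordinates (need 1 <= start <= end) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!all(df$region %in% .REGIONS)) {
    stop("region must be one of: ", paste(.REGIONS, collapse = ", "))
  }
  len <- end - start + 1L
  if (any(len < 6L | len > 30L)) {
    warning(sum(len < 6L | len > 30L),
            " site(s) outside the typical 6-30 nt length range")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$transcript),
    ranges = IRanges::IRanges(start = start, end = end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    mirna = as.character(df$mirna),
    gene = as.character(df$gene),
    region = as.character(df$region),
    tool = as.character(df$tool),
    score = if ("score" %in% names(df)) as.numeric(df$score) else
      rep(NA_real_, nrow(df)))
  gr
}

#' Read one tool's target-site predictions
#'
#' Reads the tab-separated site dialect (mandatory header with columns
#' `tool`, `mirna`, `gene`, `transcript`, `region`, `start`, `end`,
#' optional `score`; 1-based inclusive coordinates). Malformed rows are
#' rejected with their row numbers.
#'
#' @param path path to a TSV file.
#' @param tool optional tool identifier; when given, overrides/fills the
#'   `tool` column (convenient for per-tool exports lacking one).
#' @return a `GRanges` of predicted sites (see [predictedSites()]).
#' @export
readPredictions <- function(path, tool = NULL) {
  df <- .readTsv(path)
  if (!is.null(tool)) df$tool <- tool
  .requireColumns(df, c("tool", "mirna", "gene", "transcript",
                        "region", "start", "end"),
                  paste0("predictions file ", path))
  predictedSites(df)
}

#' Call consensus target sites supported by multiple tools
#'
#' A consensus site is emitted for every connected component of the
#' positional-overlap graph among predictions sharing a (miRNA,
#' transcript), provided at least `minTools` distinct tools support the
#' component. "Same location" is interpreted as an interval intersection
#' of at least `minOverlap` nucleotides. The reported interval is the
#' union (span) of the supporting intervals; the intersection is retained
#' in `intersectionStart`/`intersectionEnd` (NA when the component's
#' common core is empty, which can happen for chained overlaps).
#'
#' @param sites a `GRanges` from [predictedSites()] / [readPredictions()]
#'   (concatenate tools with `c()`).
#' @param minTools minimum number of distinct supporting tools (default 2).
#' @param minOverlap minimum intersection width in nucleotides (default 1).
#' @return a data.frame with one row per consensus site: `mirna`, `gene`,
#'   `transcript`, `region` (unique regions, comma-collapsed), `start`,
#'   `end` (the union), `intersectionStart`, `intersectionEnd`, `tools`
#'   (comma-separated, sorted), `nTools`, `nSites`.
#' @export
consensusSites <- function(sites, minTools = 2, minOverlap = 1) {
  if (minTools < 1) {
    stop("minTools must be >= 1")
  }
  if (minOverlap < 1) {
    stop("minOverlap must be >= 1")
  }
  empty <- data.frame(
    mirna = character(0), gene = character(0), transcript = character(0),
    region = character(0), start = integer(0), end = integer(0),
    intersectionStart = integer(0), intersectionEnd = integer(0),
    tools = character(0), nTools = integer(0), nSites = integer(0),
    stringsAsFactors = FALSE)
  if (length(sites) == 0) {
    return(empty)
  }
  mc <- S4Vectors::mcols(sites)
  key <- paste(mc$mirna, as.character(GenomicRanges::seqnames(sites)),
               sep = "\r")
  idx <- split(seq_along(sites), key)
  out <- vector("list", length(idx))
  for (g in seq_along(idx)) {
    ii <- idx[[g]]
    ir <- IRanges::IRanges(GenomicRanges::start(sites)[ii],
                           GenomicRanges::end(sites)[ii])
    hits <- IRanges::findOverlaps(ir, minoverlap = minOverlap,
                                  drop.self = FALSE, drop.redundant = TRUE)
    gph <- igraph::graph_from_edgelist(
      cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits)),
      directed = FALSE)
    gph <- igraph::add_vertices(
      gph, max(0L, length(ii) - igraph::vcount(gph)))
    comp <- igraph::components(gph)$membership
    rows <- lapply(split(seq_along(ii), comp), function(jj) {
      kk <- ii[jj]
      tools <- sort(unique(mc$tool[kk]))
      if (length(tools) < minTools) {
        return(NULL)
      }
      istart <- max(GenomicRanges::start(sites)[kk])
      iend <- min(GenomicRanges::end(sites)[kk])
      if (iend - istart + 1L < 1L) {
        istart <- NA_integer_
        iend <- NA_integer_
      }
      data.frame(
        mirna = mc$mirna[kk[1]],
        gene = mc$gene[kk[1]],
        transcript = as.character(GenomicRanges::seqnames(sites))[kk[1]],
        region = paste(sort(unique(mc$region[kk])), collapse = ","),
        start = min(GenomicRanges::start(sites)[kk]),
        end = max(GenomicRanges::end(sites)[kk]),
        intersectionStart = istart,
        intersectionEnd = iend,
        tools = paste(tools, collapse = ","),
        nTools = length(tools),
        nSites = length(kk),
        stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out[[g]] <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(empty)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna, res$transcript, res$start, res$end), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Candidate genes per miRNA from consensus sites
#'
#' A gene is a candidate for a miRNA if at least one consensus site links
#' them; candidates are gene sets (a gene with several sites for one miRNA
#' counts once).
#'
#' @param consensus data.frame from [consensusSites()].
#' @return a named list, miRNA -> sorted character vector of genes.
#' @export
candidatesPerMirna <- function(consensus) {
  if (nrow(consensus) == 0) {
    return(stats::setNames(list(), character(0)))
  }
  lapply(split(consensus$gene, consensus$mirna),
         function(g) sort(unique(g)))
}

#' Summarize per-miRNA candidate counts across pipeline stages
#'
#' Builds the per-miRNA count table for a funnel of filtering stages, with
#' a `Sum` row (column-wise totals over miRNAs) and a `Unique` row (the
#' number of distinct genes in the union across miRNAs, per stage). Stages
#' may be given either as per-miRNA gene sets (named list of character
#' vectors), in which case both rows are computed, or as bare per-miRNA
#' counts (numeric vector), in which case `Unique` is NA because gene
#' identities are unavailable.
#'
#' @param stageTables named list of stages; each element is either a named
#'   list (miRNA -> gene character vector) or a named/unnamed numeric
#'   vector of per-miRNA counts.
#' @return a data.frame with one row per miRNA plus `Sum` and `Unique`
#'   rows, one column per stage.
#' @examples
#' summarizeCounts(list(
#'   overlapping = c(985, 696, 555, 567, 1136, 1362)))["Sum", ]  # 5301
#' @export
summarizeCounts <- function(stageTables) {
  stopifnot(is.list(stageTables), length(stageTables) > 0,
            !is.null(names(stageTables)))
  mirnas <- unique(unlist(lapply(stageTables, function(st) {
    if (is.list(st)) names(st) else names(st)
  })))
  if (is.null(mirnas)) mirnas <- character(0)
  n <- length(stageTables)
  cols <- vector("list", n)
  for (s in seq_len(n)) {
    st <- stageTables[[s]]
    if (is.list(st)) {
      counts <- vapply(st, function(g) length(unique(g)), integer(1))
      per <- counts[match(mirnas, names(st))]
      per[is.na(per)] <- 0L
      uniq <- length(unique(unlist(st)))
    } else if (is.numeric(st)) {
      if (!is.null(names(st)) && length(mirnas) > 0) {
        per <- st[match(mirnas, names(st))]
        per[is.na(per)] <- 0
      } else {
        per <- st
        mirnas <- if (length(mirnas) == 0) {
          paste0("miRNA_", seq_along(st))
        } else {
          mirnas
        }
      }
      uniq <- NA_integer_
    } else {
      stop("stage '", names(stageTables)[s],
           "' must be a gene-set list or a numeric count vector")
    }
    cols[[s]] <- c(per, Sum = sum(per), Unique = uniq)
  }
  res <- as.data.frame(cols,
                       col.names = names(stageTables),
                       check.names = FALSE)
  rownames(res) <- c(if (length(mirnas) > 0) mirnas else character(0),
                     "Sum", "Unique")
  res
}

#' Write consensus sites as TSV
#'
#' @param consensus data.frame from [consensusSites()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeConsensusSites <- function(consensus, path) {
  .writeTsv(consensus, path)
}
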