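#' Annotate interactome nodes with expression, detection and regulation
#'
#' Builds the node table for an interactome map: each gene appearing in
#' the edge list receives a log2 atlas expression value and tier
#' (`expressed` iff log2 value >= log2(cutoff), i.e. -1 at the default
#' 0.5 FPKM/RPKM cutoff; `below_cutoff` when present below it; `unknown`
#' when absent from the atlas), a mass-spectrometry detection flag, a
#' differential direction (`up`/`down` require p < alpha and a fold
#' outside the unchanged band; `unchanged` otherwise; `not_tested` when
#' absent from the results), and provenance (`outer_segment_supplement`
#' for genes on the supplement list, otherwise `core_db`).
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` (optionally
#'   `interaction_id`).
#' @param atlas data.frame from [callExpressed()].
#' @param de gene-mapped results from [mapProteinsToGenes()] (may be NULL).
#' @param supplement character vector of supplemental genes added to the
#'   network (default none).
#' @param cutoff linear expression cutoff (default 0.5).
#' @param alpha significance level for regulation calls (default 0.05).
#' @param band percent-of-wt band treated as unchanged (default c(75, 125)).
#' @return data.frame with one row per node: `gene`, `log2_expression`,
#'   `expression_tier`, `detected_by_ms`, `de_direction`, `provenance`.
#' @export
annotateNodes <- function(edges, atlas, de = NULL, supplement = character(0),
                          cutoff = 0.5, alpha = 0.05, band = c(75, 125)) {
  .requireColumns(edges, c("gene_a", "gene_b"), "edge list")
  genes <- unique(c(as.character(edges$gene_a), as.character(edges$gene_b),
                    supplement))
  genes <- sort(genes[nzchar(genes)])
  if (anyDuplicated(atlas$gene)) {
    warning("duplicate atlas rows merged (max value kept)")
    atlas <- do.call(rbind, lapply(split(atlas, atlas$gene), function(d) {
      d[which.max(d$maxValue), , drop = FALSE]
    }))
  }
  ai <- match(genes, atlas$gene)
  log2expr <- ifelse(is.na(ai), NA_real_, log2(atlas$maxValue[ai]))
  tier <- ifelse(is.na(ai), "unknown",
                 ifelse(atlas$maxValue[ai] >= cutoff,
                        "expressed", "below_cutoff"))
  detected <- rep(FALSE, length(genes))
  direction <- rep("not_tested", length(genes))
  if (!is.null(de) && nrow(de) > 0) {
    if ("representative" %in% names(de)) {
      de <- de[de$representative, , drop = FALSE]
    }
    de <- de[!is.na(de$gene), , drop = FALSE]
    detected <- genes %in% de$gene
    for (i in which(detected)) {
      recs <- de[de$gene == genes[i], , drop = FALSE]
      sig <- !is.na(recs$p_value) & recs$p_value < alpha &
        !is.na(recs$fold_percent)
      if (any(sig & recs$fold_percent > band[2])) {
        direction[i] <- "up"
      } else if (any(sig & recs$fold_percent < band[1])) {
        direction[i] <- "down"
      } else {
        direction[i] <- "unchanged"
      }
    }
  }
  data.frame(
    gene = genes,
    log2_expression = log2expr,
    expression_tier = tier,
    detected_by_ms = detected,
    de_direction = direction,
    provenance = ifelse(genes %in% supplement,
                        "outer_segment_supplement", "core_db"),
    stringsAsFactors = FALSE)
}

#' Summarize an annotated interactome
#'
#' Tallies nodes per expression tier, detection flag, differential
#' direction and provenance, with percentages of the node total to one
#' decimal (half away from zero).
#'
#' @param nodes data.frame from [annotateNodes()].
#' @return data.frame with columns `category`, `level`, `count`,
#'   `percent`.
#' @export
overlaySummary <- function(nodes) {
  n <- nrow(nodes)
  one <- function(category, values) {
    tab <- table(values)
    data.frame(category = category, level = names(tab),
               count = as.integer(tab),
               percent = if (n > 0) {
                 roundHalfAway(100 * as.integer(tab) / n, 1)
               } else {
                 numeric(length(tab))
               },
               stringsAsFactors = FALSE)
  }
  if (n == 0) {
    return(data.frame(category = character(0), level = character(0),
                      count = integer(0), percent = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- rbind(one("expression_tier", nodes$expression_tier),
               one("detected_by_ms", nodes$detected_by_ms),
               one("de_direction", nodes$de_direction),
               one("provenance", nodes$provenance))
  rownames(res) <- NULL
  res
}

#' Write an annotated interactome as TSV plus GML
#'
#' Edge semantics are untouched (annotation only); the GML text format is
#' readable by standard network viewers.
#'
#' @param nodes data.frame from [annotateNodes()].
#' @param edges the edge list the nodes were derived from.
#' @param dir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
writeOverlay <- function(nodes, edges, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodePath <- file.path(dir, "interactome_nodes.tsv")
  edgePath <- file.path(dir, "interactome_edges.tsv")
  gmlPath <- file.path(dir, "interactome.gml")
  .writeTsv(nodes, nodePath)
  .writeTsv(edges, edgePath)
  gmlNodes <- nodes
  for (col in names(gmlNodes)) {  # GML has no boolean type
    if (is.logical(gmlNodes[[col]])) {
      gmlNodes[[col]] <- as.integer(gmlNodes[[col]])
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = gmlNodes)
  igraph::write_graph(g, gmlPath, format = "gml")
  invisible(c(nodePath, edgePath, gmlPath))
}
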