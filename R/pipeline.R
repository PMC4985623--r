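#' Default pipeline configuration
#'
#' Returns the effective configuration list: input paths (all NULL until
#' set), thresholds at the pipeline defaults (expression cutoff 0.5
#' FPKM/RPKM; inverse-pair bands of 75-125% of wild type with raw
#' p < 0.05; over-representation with minimum overlap 2 and p < 0.05;
#' regulated-set bounds of >2.0-fold and <0.5-fold; miR-CATCH detection
#' limit Ct 37, enrichment call at 1.5-fold, probe off-target bound 15
#' nt), a seed, and an output directory.
#'
#' @param ... named overrides of any default element.
#' @return a configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    predictions = NULL, atlas = NULL, biotypes = NULL,
    quant = NULL, protein_map = NULL, mirna_changes = NULL,
    gmt = NULL, edges = NULL, ct = NULL,
    expression_cutoff = 0.5,
    alpha = 0.05,
    mirna_band = c(75, 125),
    protein_band = c(75, 125),
    up_fold = 2.0, down_fold = 0.5,
    min_overlap = 2, p_cut = 0.05,
    detection_limit = 37, enrich_cut = 1.5, max_stretch = 15,
    seed = 1L,
    outdir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipelineConfig()]; unset keys take the defaults and
#' command-style overrides can be supplied via `...`.
#'
#' @param path YAML file.
#' @param ... named overrides applied after reading.
#' @return a configuration list.
#' @export
readPipelineConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, utils::modifyList(raw, list(...)))
}

.stageLog <- function(stage, msg) {
  message(sprintf("[%s] %s :: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg))
}

.needInput <- function(cfg, key, stage) {
  p <- cfg[[key]]
  if (is.null(p)) {
    stop("pipeline stage '", stage, "': missing input '", key, "'")
  }
  for (f in p) {
    if (!file.exists(f)) {
      stop("pipeline stage '", stage, "': input file not found: ", f)
    }
  }
  p
}

#' Run the discovery pipeline end-to-end
#'
#' Executes the stages in dependency order: consensus target calling,
#' expression filtering (protein-coding genes at the atlas cutoff),
#' differential protein abundance with gene mapping, inverse-pair
#' discovery, and pathway over-representation of the up-/down-regulated
#' protein sets against the identified-gene background. The miR-CATCH
#' stage (Ct table present) and interactome overlay (edge list present)
#' run independently when their inputs are configured. All tabular
#' outputs are written as TSV into `outdir` along with the effective
#' configuration (YAML echo); reruns with identical inputs and
#' configuration are byte-identical.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()],
#'   with input paths set.
#' @return invisibly, a list of stage results: `consensus`, `counts`,
#'   `expressed`, `de`, `pairs`, `sharedTargets`, `ora_up`, `ora_down`,
#'   and when configured `mircatch`, `overlay`.
#' @export
runPipeline <- function(config) {
  stopifnot(is.list(config))
  out <- list()
  writeOut <- !is.null(config$outdir)
  if (writeOut && !dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }

  # stage: consensus target calling
  predPaths <- .needInput(config, "predictions", "consensus")
  sites <- do.call(c, lapply(predPaths, readPredictions))
  .stageLog("consensus", paste(length(sites), "predicted site rows"))
  consensus <- consensusSites(sites)
  candidates <- candidatesPerMirna(consensus)
  .stageLog("consensus", paste(nrow(consensus), "consensus sites,",
                               length(candidates), "miRNAs"))

  # stage: expression filter
  atlasPath <- .needInput(config, "atlas", "expressed")
  atlas <- callExpressed(readAtlas(atlasPath),
                         cutoff = config$expression_cutoff)
  expressed <- atlas[atlas$expressed, , drop = FALSE]
  if (!is.null(config$biotypes)) {
    bio <- .readTsv(.needInput(config, "biotypes", "expressed"))
    expressed <- suppressWarnings(filterProteinCoding(expressed, bio))
  }
  .stageLog("expressed", paste(nrow(expressed), "expressed genes"))
  candidatesExpr <- lapply(candidates,
                           function(g) intersect(g, expressed$gene))
  counts <- summarizeCounts(list(
    overlapping_sites = candidates,
    retina_expressed = candidatesExpr))

  # stage: differential abundance + gene mapping
  quantPath <- .needInput(config, "quant", "de")
  pe <- readProteinQuant(quantPath)
  de <- suppressWarnings(differentialAbundance(pe))
  mapPath <- .needInput(config, "protein_map", "de")
  de <- mapProteinsToGenes(de, .readTsv(mapPath))
  .stageLog("de", paste(nrow(de), "protein/fraction results,",
                        sum(!is.na(de$p_value) &
                              de$p_value < config$alpha), "at p <",
                        config$alpha))

  # stage: inverse-pair discovery
  mirnaPath <- .needInput(config, "mirna_changes", "pairs")
  thresholds <- pairThresholds(alpha = config$alpha,
                               mirnaBand = config$mirna_band,
                               proteinBand = config$protein_band)
  pairs <- suppressWarnings(
    inversePairs(readMirnaChanges(mirnaPath), de, candidatesExpr,
                 thresholds))
  shared <- sharedTargets(pairs)
  .stageLog("pairs", paste(nrow(pairs), "candidate pairs"))

  # stage: over-representation (optional, needs gene sets)
  oraUp <- oraDown <- NULL
  if (!is.null(config$gmt)) {
    sets <- readGmt(.needInput(config, "gmt", "ora"))
    background <- sort(unique(de$gene[!is.na(de$gene)]))
    reg <- suppressWarnings(
      selectRegulated(de, alpha = config$alpha,
                      upFold = config$up_fold,
                      downFold = config$down_fold))
    oraUp <- overrepresentation(reg$up, background, sets,
                                minOverlap = config$min_overlap,
                                pCut = config$p_cut)
    oraDown <- overrepresentation(reg$down, background, sets,
                                  minOverlap = config$min_overlap,
                                  pCut = config$p_cut)
    .stageLog("ora", paste(nrow(oraUp), "up /", nrow(oraDown),
                           "down enriched sets"))
  }

  # independent stage: miR-CATCH quantification
  mircatch <- NULL
  if (!is.null(config$ct)) {
    ct <- readCtTable(.needInput(config, "ct", "mircatch"))
    mirnaAssays <- setdiff(unique(ct$assay), c("target_mrna", "Actb"))
    mircatch <- mirnaFoldTable(ct, mirnaAssays,
                               detectionLimit = config$detection_limit)
    .stageLog("mircatch", paste(nrow(mircatch), "miRNA assays quantified"))
  }

  # independent stage: interactome overlay
  overlay <- NULL
  if (!is.null(config$edges)) {
    edges <- .readTsv(.needInput(config, "edges", "overlay"))
    nodes <- suppressWarnings(
      annotateNodes(edges, atlas, de, cutoff = config$expression_cutoff,
                    alpha = config$alpha, band = config$protein_band))
    overlay <- list(nodes = nodes, summary = overlaySummary(nodes))
    .stageLog("overlay", paste(nrow(nodes), "nodes annotated"))
  }

  out <- list(consensus = consensus, counts = counts,
              expressed = expressed, de = de, pairs = pairs,
              sharedTargets = shared, ora_up = oraUp, ora_down = oraDown,
              mircatch = mircatch, overlay = overlay)

  if (writeOut) {
    .writeTsv(consensus, file.path(config$outdir, "consensus_sites.tsv"))
    countsOut <- cbind(id = rownames(counts), counts)
    .writeTsv(countsOut, file.path(config$outdir, "stage_counts.tsv"))
    .writeTsv(expressed, file.path(config$outdir, "expressed_genes.tsv"))
    .writeTsv(de, file.path(config$outdir, "differential_abundance.tsv"))
    .writeTsv(pairs, file.path(config$outdir, "candidate_pairs.tsv"))
    sharedOut <- cbind(mirna = rownames(shared), as.data.frame(shared))
    .writeTsv(sharedOut, file.path(config$outdir, "shared_targets.tsv"))
    if (!is.null(oraUp)) {
      .writeTsv(oraUp, file.path(config$outdir, "ora_up.tsv"))
      .writeTsv(oraDown, file.path(config$outdir, "ora_down.tsv"))
    }
    if (!is.null(mircatch)) {
      .writeTsv(mircatch, file.path(config$outdir, "mircatch_folds.tsv"))
    }
    if (!is.null(overlay)) {
      writeOverlay(overlay$nodes, edges, config$outdir)
      .writeTsv(overlay$summary,
                file.path(config$outdir, "overlay_summary.tsv"))
    }
    yaml::write_yaml(config, file.path(config$outdir, "effective_config.yaml"))
  }
  invisible(out)
}
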