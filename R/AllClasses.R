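#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Simulation configuration
#'
#' Holds every tunable of the synthetic-study generator. A single integer
#' seed governs all generators; each simulated table draws from its own
#' deterministic sub-stream so regenerating one table never perturbs the
#' others. Defaults encode the study conditions the pipeline is designed
#' for: four replicates per genotype group and fraction, log2-normal
#' abundance noise of 0.25, qPCR Ct noise of 0.3 cycles, three prediction
#' tools, and the six dysregulated retinal miRNAs with their published
#' fold-changes versus wild type.
#'
#' @slot seed integer master seed.
#' @slot nGenes number of genes in the simulated universe.
#' @slot nMirnas number of miRNAs with predicted sites.
#' @slot nTools number of target-prediction tools (default 3).
#' @slot nSites total number of distinct target-site loci to plant.
#' @slot plantedConsensusFraction fraction of site loci supported by >= 2
#'   tools at overlapping positions; the rest are decoys.
#' @slot expressedFraction fraction of genes whose atlas maximum is at or
#'   above the expression cutoff.
#' @slot codingFraction fraction of genes annotated protein-coding.
#' @slot nReplicates replicates per group per fraction (>= 2).
#' @slot plantedFoldMap named numeric, gene -> true mutant/wt abundance
#'   ratio; genes absent from the map have ratio 1.
#' @slot abundanceNoiseSd standard deviation of log2 abundance noise.
#' @slot mirnaFoldMap named numeric, miRNA -> expression in mutant as
#'   percent of wild type.
#' @slot ctNoiseSd standard deviation (cycles) of additive Ct noise.
#' @slot nCtReplicates qPCR replicates per sample arm.
#' @slot plantedEnrichmentMap named numeric, miRNA assay -> true
#'   capture/scrambled fold; `Inf` plants a scrambled arm below detection.
#' @slot mrnaEnrichment true capture/scrambled fold of the captured mRNA.
#' @slot dropoutCt Ct threshold beyond which an assay is recorded as not
#'   amplified (explicit missing marker, never a sentinel number).
#' @seealso [simConfig()], [simulateStudy()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nGenes = "integer",
  nMirnas = "integer",
  nTools = "integer",
  nSites = "integer",
  plantedConsensusFraction = "numeric",
  expressedFraction = "numeric",
  codingFraction = "numeric",
  nReplicates = "integer",
  plantedFoldMap = "numeric",
  abundanceNoiseSd = "numeric",
  mirnaFoldMap = "numeric",
  ctNoiseSd = "numeric",
  nCtReplicates = "integer",
  plantedEnrichmentMap = "numeric",
  mrnaEnrichment = "numeric",
  dropoutCt = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  counts <- c(nGenes = object@nGenes, nMirnas = object@nMirnas,
              nTools = object@nTools, nSites = object@nSites,
              nCtReplicates = object@nCtReplicates)
  bad <- names(counts)[is.na(counts) | counts < 1L]
  if (length(bad) > 0) {
    msg <- c(msg, paste0("counts must be positive: ",
                         paste(bad, collapse = ", ")))
  }
  fracs <- c(plantedConsensusFraction = object@plantedConsensusFraction,
             expressedFraction = object@expressedFraction,
             codingFraction = object@codingFraction)
  badf <- names(fracs)[is.na(fracs) | fracs < 0 | fracs > 1]
  if (length(badf) > 0) {
    msg <- c(msg, paste0("fractions must lie in [0, 1]: ",
                         paste(badf, collapse = ", ")))
  }
  if (is.na(object@nReplicates) || object@nReplicates < 2L) {
    msg <- c(msg, "nReplicates must be >= 2")
  }
  if (object@abundanceNoiseSd < 0 || object@ctNoiseSd < 0) {
    msg <- c(msg, "noise standard deviations must be >= 0")
  }
  if (length(object@plantedFoldMap) > 0 &&
      (is.null(names(object@plantedFoldMap)) ||
       any(object@plantedFoldMap <= 0))) {
    msg <- c(msg, "plantedFoldMap must be a named vector of positive ratios")
  }
  if (length(object@mirnaFoldMap) == 0 ||
      is.null(names(object@mirnaFoldMap)) || any(object@mirnaFoldMap <= 0)) {
    msg <- c(msg, "mirnaFoldMap must be a named vector of positive percents")
  }
  if (length(object@plantedEnrichmentMap) > 0 &&
      (is.null(names(object@plantedEnrichmentMap)) ||
       any(object@plantedEnrichmentMap <= 0))) {
    msg <- c(msg, "plantedEnrichmentMap values must be positive")
  }
  if (object@mrnaEnrichment <= 0) {
    msg <- c(msg, "mrnaEnrichment must be positive")
  }
  if (object@dropoutCt <= 0) {
    msg <- c(msg, "dropoutCt must be positive")
  }
  if (length(msg) > 0) msg else TRUE
})

#' Simulated multi-omic study with recorded planted truth
#'
#' Container produced by [simulateStudy()]: every input table the pipeline
#' consumes, plus the planted truth against which stage outputs can be
#' checked. Accessors: [plantedTruth()], [simConfigOf()].
#'
#' @slot config the [SimConfig-class] that generated the study.
#' @slot predictions per-tool target-site table (long data.frame).
#' @slot atlas expression atlas records (gene, dataset, value).
#' @slot biotypes gene -> biotype table.
#' @slot proteome a [ProteomicsExperiment-class] of replicate abundances.
#' @slot proteinMap protein_id -> gene mapping table.
#' @slot mirnaChanges miRNA fold-change table (percent of wild type).
#' @slot ct qPCR Ct table (assay, sample, replicate, ct; NA = not amplified).
#' @slot truth list of planted truths (consensus sites, expressed genes,
#'   coding genes, true folds, inverse pairs, true enrichments).
#' @export
setClass("SimulatedStudy", representation(
  config = "SimConfig",
  predictions = "data.frame",
  atlas = "data.frame",
  biotypes = "data.frame",
  proteome = "ANY",
  proteinMap = "data.frame",
  mirnaChanges = "data.frame",
  ct = "data.frame",
  truth = "list"
))

setValidity("SimulatedStudy", function(object) {
  need <- c("consensusSites", "expressedGenes", "codingGenes",
            "trueFolds", "inversePairs", "trueEnrichments")
  missing <- setdiff(need, names(object@truth))
  if (length(missing) > 0) {
    return(paste0("truth is missing: ", paste(missing, collapse = ", ")))
  }
  TRUE
})

setMethod("show", "SimulatedStudy", function(object) {
  cfg <- object@config
  cat("SimulatedStudy (seed ", cfg@seed, ")\n", sep = "")
  cat("  predictions : ", nrow(object@predictions), " site rows, ",
      cfg@nTools, " tools\n", sep = "")
  cat("  atlas       : ", length(unique(object@atlas$gene)), " genes, ",
      length(unique(object@atlas$dataset)), " datasets\n", sep = "")
  cat("  proteome    : ", nrow(object@proteome), " proteins x ",
      ncol(object@proteome), " runs\n", sep = "")
  cat("  ct table    : ", length(unique(object@ct$assay)), " assays\n",
      sep = "")
  cat("  planted     : ", nrow(object@truth$consensusSites),
      " consensus sites, ", nrow(object@truth$inversePairs),
      " inverse pairs\n", sep = "")
  invisible(NULL)
})

#' Label-free proteomics replicate experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `abundance` assay (proteins x runs) with column metadata `fraction`
#' (whole or membrane), `group` (mutant or wt) and `replicate`. The
#' validity method enforces the design required by
#' [differentialAbundance()].
#'
#' @export
setClass("ProteomicsExperiment",
         contains = "SummarizedExperiment")

setValidity("ProteomicsExperiment", function(object) {
  msg <- character(0)
  if (!"abundance" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'abundance' is required")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("fraction", "group", "replicate")
  missing <- setdiff(need, names(cd))
  if (length(missing) > 0) {
    msg <- c(msg, paste0("colData must contain: ",
                         paste(missing, collapse = ", ")))
  } else {
    if (!all(cd$fraction %in% c("whole", "membrane"))) {
      msg <- c(msg, "fraction must be 'whole' or 'membrane'")
    }
    if (!all(cd$group %in% c("mutant", "wt"))) {
      msg <- c(msg, "group must be 'mutant' or 'wt'")
    }
    key <- paste(cd$fraction, cd$group, cd$replicate)
    if (anyDuplicated(key)) {
      msg <- c(msg, "replicate indices must be unique within (fraction, group)")
    }
  }
  if ("abundance" %in% SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (any(a < 0, na.rm = TRUE)) {
      msg <- c(msg, "abundances must be non-negative")
    }
  }
  if (length(msg) > 0) msg else TRUE
})
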