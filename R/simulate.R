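#' Build a simulation configuration
#'
#' Constructs and validates a [SimConfig-class]. The defaults are the
#' study conditions the pipeline emulates: six retinal miRNAs with the
#' published mutant-versus-wild-type fold-changes (the miR-183/96/182
#' cluster down to ~50%, miR-1/133 up ~5-fold, miR-142 up ~4-fold), three
#' target-prediction tools, four replicates per genotype group and
#' fraction with log2-normal abundance noise of 0.25, triplicate qPCR
#' with 0.3-cycle Ct noise, a capture-versus-scrambled mRNA enrichment of
#' ~50-fold, and panel-scale miRNA enrichments (an infinite planted fold
#' plants a scrambled arm below the detection limit, exercising the
#' not-amplified semantics).
#'
#' @param seed integer master seed; one seed governs every generator via
#'   deterministic per-table sub-streams.
#' @param nGenes,nMirnas,nTools,nSites universe sizes (see
#'   [SimConfig-class]).
#' @param plantedConsensusFraction fraction of site loci planted as
#'   multi-tool overlapping consensus sites (default 0.3).
#' @param expressedFraction fraction of genes expressed at the atlas
#'   cutoff (default 0.63).
#' @param codingFraction fraction of genes annotated protein-coding
#'   (default 0.89).
#' @param nReplicates replicates per group per fraction (default 4).
#' @param plantedFoldMap named gene -> mutant/wt abundance ratio; empty
#'   (default) lets [simulateStudy()] plant folds consistent with the
#'   planted consensus sites and miRNA directions.
#' @param abundanceNoiseSd log2 abundance noise sd (default 0.25).
#' @param mirnaFoldMap named miRNA -> percent of wild type.
#' @param ctNoiseSd additive Ct noise sd in cycles (default 0.3).
#' @param nCtReplicates qPCR replicates per arm (default 3).
#' @param plantedEnrichmentMap named miRNA assay -> true
#'   capture/scrambled fold; `Inf` plants an undetectable scrambled arm.
#' @param mrnaEnrichment true capture/scrambled fold of the captured
#'   mRNA (default 50).
#' @param dropoutCt Ct beyond which an assay is recorded not amplified
#'   (default 40).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 400L,
                      nMirnas = 6L,
                      nTools = 3L,
                      nSites = 200L,
                      plantedConsensusFraction = 0.3,
                      expressedFraction = 0.63,
                      codingFraction = 0.89,
                      nReplicates = 4L,
                      plantedFoldMap = numeric(0),
                      abundanceNoiseSd = 0.25,
                      mirnaFoldMap = c(
                        "miR-1" = 550, "miR-133" = 500, "miR-142" = 400,
                        "miR-183" = 50, "miR-96" = 50, "miR-182" = 50),
                      ctNoiseSd = 0.3,
                      nCtReplicates = 3L,
                      plantedEnrichmentMap = c(
                        "miR-103-3p" = 9.54, "miR-96-5p" = 5.07,
                        "miR-182-5p" = 3.63, "miR-125a-5p" = 7.38,
                        "miR-30c-5p" = 3.10, "miR-151-3p" = Inf,
                        "miR-16-5p" = 1.0),
                      mrnaEnrichment = 50,
                      dropoutCt = 40) {
  cfg <- methods::new(
    "SimConfig",
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    nMirnas = as.integer(nMirnas), nTools = as.integer(nTools),
    nSites = as.integer(nSites),
    plantedConsensusFraction = plantedConsensusFraction,
    expressedFraction = expressedFraction,
    codingFraction = codingFraction,
    nReplicates = as.integer(nReplicates),
    plantedFoldMap = plantedFoldMap,
    abundanceNoiseSd = abundanceNoiseSd,
    mirnaFoldMap = mirnaFoldMap,
    ctNoiseSd = ctNoiseSd,
    nCtReplicates = as.integer(nCtReplicates),
    plantedEnrichmentMap = plantedEnrichmentMap,
    mrnaEnrichment = mrnaEnrichment,
    dropoutCt = dropoutCt)
  methods::validObject(cfg)
  if (cfg@nSites > cfg@nGenes * cfg@nMirnas) {
    stop("nSites must not exceed nGenes * nMirnas")
  }
  cfg
}

.simGenes <- function(config) sprintf("g%05d", seq_len(config@nGenes))

.simMirnas <- function(config) {
  base <- names(config@mirnaFoldMap)
  if (config@nMirnas <= length(base)) {
    base[seq_len(config@nMirnas)]
  } else {
    c(base, sprintf("miR-sim%02d", seq_len(config@nMirnas - length(base))))
  }
}

.simTools <- function(config) {
  base <- c("microT", "miRanda", "TargetScan")
  if (config@nTools <= 3L) {
    base[seq_len(config@nTools)]
  } else {
    c(base, sprintf("tool%02d", seq_len(config@nTools - 3L)))
  }
}

#' Simulate per-tool target-site prediction tables
#'
#' Plants `nSites * plantedConsensusFraction` (rounded) consensus loci,
#' each predicted by at least two tools with mutually overlapping
#' intervals on the same transcript, and fills the remainder with decoys:
#' alternately single-tool sites and two-tool sites at distant,
#' non-overlapping positions (which count for the "predicted by >= 2
#' methods" stage but not the overlapping-site stage). Each site locus
#' occupies its own (miRNA, gene) pair, so overlap components never merge
#' across loci.
#'
#' @param config a [SimConfig-class].
#' @return list with `predictions` (long data.frame: tool, mirna, gene,
#'   transcript, region, start, end, score) and `truth` (list with
#'   `consensusSites` and `decoys` data.frames).
#' @export
simulatePredictions <- function(config) {
  methods::validObject(config)
  .withSubstream(config@seed, 1L, {
    genes <- .simGenes(config)
    mirnas <- .simMirnas(config)
    tools <- .simTools(config)
    nCons <- round(config@nSites * config@plantedConsensusFraction)
    nDecoy <- config@nSites - nCons
    pairIdx <- sample.int(config@nGenes * config@nMirnas, config@nSites)
    pairGene <- genes[((pairIdx - 1L) %% config@nGenes) + 1L]
    pairMirna <- mirnas[((pairIdx - 1L) %/% config@nGenes) + 1L]
    rows <- list()
    truthCons <- list()
    truthDecoy <- list()
    for (i in seq_len(config@nSites)) {
      g <- pairGene[i]; m <- pairMirna[i]
      tx <- paste0("t_", g)
      region <- sample(.REGIONS, 1, prob = c(0.1, 0.3, 0.6))
      w <- sample(7:22, 1)
      s <- sample(200:1500, 1)
      if (i <= nCons) {
        k <- if (config@nTools == 2L) 2L else sample(2:config@nTools, 1)
        tls <- sort(sample(tools, k))
        shift <- c(0L, sample(-3:3, k - 1, replace = TRUE))
        st <- s + shift
        en <- st + w - 1L
        for (j in seq_len(k)) {
          rows[[length(rows) + 1L]] <- data.frame(
            tool = tls[j], mirna = m, gene = g, transcript = tx,
            region = region, start = st[j], end = en[j],
            score = round(stats::runif(1), 3), stringsAsFactors = FALSE)
        }
        truthCons[[length(truthCons) + 1L]] <- data.frame(
          mirna = m, gene = g, transcript = tx,
          start = min(st), end = max(en),
          tools = paste(tls, collapse = ","), stringsAsFactors = FALSE)
      } else {
        type <- if ((i - nCons) %% 2L == 1L) "single_tool" else
          "non_overlapping"
        if (type == "single_tool") {
          tls <- sample(tools, 1)
          st <- s; en <- s + w - 1L
        } else {
          tls <- sort(sample(tools, 2))
          st <- c(s, s + w + 100L)
          en <- st + w - 1L
        }
        for (j in seq_along(tls)) {
          rows[[length(rows) + 1L]] <- data.frame(
            tool = tls[j], mirna = m, gene = g, transcript = tx,
            region = region, start = st[j], end = en[j],
            score = round(stats::runif(1), 3), stringsAsFactors = FALSE)
        }
        truthDecoy[[length(truthDecoy) + 1L]] <- data.frame(
          mirna = m, gene = g, transcript = tx, type = type,
          stringsAsFactors = FALSE)
      }
    }
    predictions <- do.call(rbind, rows)
    rownames(predictions) <- NULL
    consensus <- if (length(truthCons) > 0) {
      do.call(rbind, truthCons)
    } else {
      data.frame(mirna = character(0), gene = character(0),
                 transcript = character(0), start = integer(0),
                 end = integer(0), tools = character(0),
                 stringsAsFactors = FALSE)
    }
    decoys <- if (length(truthDecoy) > 0) {
      do.call(rbind, truthDecoy)
    } else {
      data.frame(mirna = character(0), gene = character(0),
                 transcript = character(0), type = character(0),
                 stringsAsFactors = FALSE)
    }
    list(predictions = predictions,
         truth = list(consensusSites = consensus, decoys = decoys))
  })
}

#' Simulate a multi-dataset expression atlas and biotype table
#'
#' Expressed genes receive a maximum value at or above the cutoff across
#' three datasets (log-scale spread mimicking FPKM/RPKM libraries);
#' non-expressed genes stay strictly below it. A biotype table marks the
#' protein-coding fraction. Genes listed in `forceExpressed` are made
#' both expressed and protein-coding (used to keep planted inverse-pair
#' genes inside the pipeline funnel).
#'
#' @param config a [SimConfig-class].
#' @param forceExpressed genes guaranteed expressed and coding.
#' @param cutoff the expression cutoff emulated (default 0.5).
#' @return list with `atlas` (gene, dataset, value), `biotypes` (gene,
#'   biotype) and `truth` (list with `expressedGenes`, `codingGenes`).
#' @export
simulateAtlas <- function(config, forceExpressed = character(0),
                          cutoff = 0.5) {
  methods::validObject(config)
  .withSubstream(config@seed, 2L, {
    genes <- .simGenes(config)
    forceExpressed <- intersect(forceExpressed, genes)
    nExpr <- max(round(config@nGenes * config@expressedFraction),
                 length(forceExpressed))
    pool <- setdiff(genes, forceExpressed)
    expressed <- sort(c(forceExpressed,
                        sample(pool, nExpr - length(forceExpressed))))
    datasets <- c("ds1", "ds2", "ds3")
    rows <- lapply(genes, function(g) {
      if (g %in% expressed) {
        vmax <- cutoff * 2^stats::rexp(1, rate = 0.25)
        v <- c(vmax, vmax * stats::runif(2, 0, 1))
      } else {
        vmax <- stats::runif(1, 0, cutoff * 0.98)
        v <- c(vmax, vmax * stats::runif(2, 0, 1))
      }
      data.frame(gene = g, dataset = datasets,
                 value = round(v[sample.int(3)], 4),
                 stringsAsFactors = FALSE)
    })
    atlas <- do.call(rbind, rows)
    rownames(atlas) <- NULL
    nCoding <- max(round(config@nGenes * config@codingFraction),
                   length(forceExpressed))
    poolC <- setdiff(genes, forceExpressed)
    coding <- sort(c(forceExpressed,
                     sample(poolC, nCoding - length(forceExpressed))))
    biotypes <- data.frame(
      gene = genes,
      biotype = ifelse(genes %in% coding, "protein_coding", "lincRNA"),
      stringsAsFactors = FALSE)
    list(atlas = atlas, biotypes = biotypes,
         truth = list(expressedGenes = expressed, codingGenes = coding))
  })
}

#' Simulate replicate protein abundances for two fractions
#'
#' Per gene and fraction, wild-type replicates are log2-normal around a
#' gene-specific base abundance and mutant replicates around base times
#' the planted fold (1 for genes absent from `plantedFoldMap`). Because
#' the same multiplicative noise law applies to both groups, the ratio of
#' group expectations equals the planted fold exactly; at zero noise the
#' estimated fold is exact.
#'
#' @param config a [SimConfig-class]; `nReplicates` must be >= 2.
#' @return list with `proteome` (a [ProteomicsExperiment-class]),
#'   `proteinMap` (protein_id -> gene) and `truth` (list with
#'   `trueFolds`).
#' @export
simulateProteome <- function(config) {
  methods::validObject(config)
  .withSubstream(config@seed, 3L, {
    genes <- .simGenes(config)
    folds <- stats::setNames(rep(1, length(genes)), genes)
    known <- intersect(names(config@plantedFoldMap), genes)
    folds[known] <- config@plantedFoldMap[known]
    n <- config@nReplicates
    quant <- list()
    for (fr in c("whole", "membrane")) {
      base <- 2^stats::rnorm(length(genes), mean = 15, sd = 2)
      for (gi in seq_along(genes)) {
        wt <- base[gi] * 2^stats::rnorm(n, 0, config@abundanceNoiseSd)
        mu <- base[gi] * folds[gi] *
          2^stats::rnorm(n, 0, config@abundanceNoiseSd)
        quant[[length(quant) + 1L]] <- data.frame(
          protein_id = paste0("p_", genes[gi]),
          fraction = fr,
          group = rep(c("wt", "mutant"), each = n),
          replicate = rep(seq_len(n), 2),
          abundance = c(wt, mu),
          stringsAsFactors = FALSE)
      }
    }
    quant <- do.call(rbind, quant)
    proteinMap <- data.frame(protein_id = paste0("p_", genes),
                             gene = genes, stringsAsFactors = FALSE)
    list(proteome = proteomicsExperiment(quant),
         proteinMap = proteinMap,
         truth = list(trueFolds = folds))
  })
}

#' Simulate a qPCR Ct table for capture versus scrambled samples
#'
#' Generates triplicate (by default) Ct values for the captured mRNA, a
#' housekeeping normalizer (`Actb`, identical in both arms up to noise)
#' and each miRNA assay in `plantedEnrichmentMap`. The capture arm mean
#' sits `log2(fold)` cycles below the scrambled arm, so the
#' capture-versus-scrambled mean Ct difference equals `-log2(fold)` plus
#' noise. A planted fold of `Inf` places the scrambled arm beyond
#' `dropoutCt`; any generated Ct beyond `dropoutCt` is recorded as the
#' explicit not-amplified marker `NA`.
#'
#' @param config a [SimConfig-class].
#' @return list with `ct` (assay, sample, replicate, ct) and `truth`
#'   (list with `trueEnrichments`, `mrnaEnrichment`).
#' @export
simulateCtMatrix <- function(config) {
  methods::validObject(config)
  .withSubstream(config@seed, 4L, {
    n <- config@nCtReplicates
    rows <- list()
    emit <- function(assay, scrMean, fold) {
      capMean <- if (is.finite(fold)) scrMean - log2(fold) else scrMean - 8
      scrBase <- if (is.finite(fold)) scrMean else config@dropoutCt + 3
      for (sample in c("capture", "scrambled")) {
        mu <- if (sample == "capture") capMean else scrBase
        ctv <- mu + stats::rnorm(n, 0, config@ctNoiseSd)
        ctv[ctv > config@dropoutCt] <- NA_real_
        rows[[length(rows) + 1L]] <<- data.frame(
          assay = assay, sample = sample, replicate = seq_len(n),
          ct = round(ctv, 3), stringsAsFactors = FALSE)
      }
    }
    emit("target_mrna", scrMean = 30, fold = config@mrnaEnrichment)
    emit("Actb", scrMean = 20, fold = 1)
    scrMeans <- stats::runif(length(config@plantedEnrichmentMap), 28, 33)
    for (i in seq_along(config@plantedEnrichmentMap)) {
      emit(names(config@plantedEnrichmentMap)[i], scrMeans[i],
           config@plantedEnrichmentMap[i])
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    list(ct = ct,
         truth = list(trueEnrichments = config@plantedEnrichmentMap,
                      mrnaEnrichment = config@mrnaEnrichment))
  })
}

#' Simulate miRNA fold-change records
#'
#' Renders the configured miRNA fold map as the table the pair-discovery
#' stage reads. The photoreceptor column is an annotation-only amplified
#' version of the retina fold (changes are typically stronger in the
#' affected cell type).
#'
#' @param config a [SimConfig-class].
#' @return data.frame: `mirna`, `fold_retina_percent`,
#'   `fold_photoreceptor_percent`.
#' @export
simulateMirnaChanges <- function(config) {
  mirnas <- .simMirnas(config)
  fold <- config@mirnaFoldMap[mirnas]
  fold[is.na(fold)] <- 100
  names(fold) <- mirnas
  data.frame(
    mirna = mirnas,
    fold_retina_percent = as.numeric(fold),
    fold_photoreceptor_percent = as.numeric(
      ifelse(fold < 100, fold * 1.2, fold * 3.5)),
    stringsAsFactors = FALSE)
}

#' Simulate a complete multi-omic study with planted truth
#'
#' Runs every generator under one master seed and plants a consistent
#' cross-stage truth: when `plantedFoldMap` is empty, each planted
#' consensus pair whose miRNA is dysregulated (outside the 75-125% band)
#' receives a protein fold in the opposite direction (2-4x up for
#' down-regulated miRNAs, 0.25-0.5x for up-regulated ones); genes of the
#' resulting inverse pairs are forced expressed and protein-coding so
#' they survive the pipeline funnel. The recorded `inversePairs` truth is
#' the exact set of (miRNA, gene) pairs satisfying the inverse rule under
#' the planted folds, computable downstream in the noiseless limit.
#'
#' @param config a [SimConfig-class].
#' @return a [SimulatedStudy-class].
#' @export
simulateStudy <- function(config) {
  methods::validObject(config)
  preds <- simulatePredictions(config)
  cons <- preds$truth$consensusSites
  foldMap <- config@plantedFoldMap
  if (length(foldMap) == 0 && nrow(cons) > 0) {
    foldMap <- .withSubstream(config@seed, 5L, {
      mirFold <- config@mirnaFoldMap
      fm <- numeric(0)
      for (i in seq_len(nrow(cons))) {
        m <- cons$mirna[i]; g <- cons$gene[i]
        mf <- if (m %in% names(mirFold)) mirFold[[m]] else 100
        if (mf >= 75 && mf <= 125) next
        if (g %in% names(fm)) next  # first assignment wins
        fm[g] <- if (mf < 75) {
          stats::runif(1, 2, 4)        # miRNA down -> protein up
        } else {
          stats::runif(1, 0.25, 0.5)   # miRNA up -> protein down
        }
      }
      fm
    })
  }
  # exact inverse-pair truth under the planted folds
  inv <- data.frame(mirna = character(0), gene = character(0),
                    direction = character(0), stringsAsFactors = FALSE)
  if (nrow(cons) > 0 && length(foldMap) > 0) {
    mirFold <- config@mirnaFoldMap
    keep <- vapply(seq_len(nrow(cons)), function(i) {
      m <- cons$mirna[i]; g <- cons$gene[i]
      if (!m %in% names(mirFold) || !g %in% names(foldMap)) return(FALSE)
      mf <- mirFold[[m]]; pf <- foldMap[[g]] * 100
      (mf < 75 && pf > 125) || (mf > 125 && pf < 75)
    }, logical(1))
    if (any(keep)) {
      ck <- cons[keep, , drop = FALSE]
      inv <- unique(data.frame(
        mirna = ck$mirna, gene = ck$gene,
        direction = ifelse(mirFold[ck$mirna] > 125,
                           "mirna_up_protein_down",
                           "mirna_down_protein_up"),
        stringsAsFactors = FALSE))
      inv <- inv[order(inv$mirna, inv$gene), , drop = FALSE]
      rownames(inv) <- NULL
    }
  }
  cfg2 <- config
  cfg2@plantedFoldMap <- foldMap
  atl <- simulateAtlas(cfg2, forceExpressed = unique(inv$gene))
  prot <- simulateProteome(cfg2)
  ctm <- simulateCtMatrix(cfg2)
  methods::new(
    "SimulatedStudy",
    config = cfg2,
    predictions = preds$predictions,
    atlas = atl$atlas,
    biotypes = atl$biotypes,
    proteome = prot$proteome,
    proteinMap = prot$proteinMap,
    mirnaChanges = simulateMirnaChanges(cfg2),
    ct = ctm$ct,
    truth = list(
      consensusSites = cons,
      decoys = preds$truth$decoys,
      expressedGenes = atl$truth$expressedGenes,
      codingGenes = atl$truth$codingGenes,
      trueFolds = prot$truth$trueFolds,
      inversePairs = inv,
      trueEnrichments = ctm$truth$trueEnrichments,
      mrnaEnrichment = ctm$truth$mrnaEnrichment))
}

#' Write the simulated study in the dialects the pipeline reads
#'
#' Emits predictions, atlas, biotypes, protein quantifications (long
#' TSV), protein-gene map, miRNA changes and the Ct table as TSV, plus
#' the planted truth as structured YAML text.
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if absent).
#' @return named character vector of paths, invisibly.
#' @export
writeSimulatedStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(study@proteome, "abundance")
  cd <- SummarizedExperiment::colData(study@proteome)
  quant <- data.frame(
    protein_id = rep(rownames(m), times = ncol(m)),
    fraction = rep(cd$fraction, each = nrow(m)),
    group = rep(cd$group, each = nrow(m)),
    replicate = rep(cd$replicate, each = nrow(m)),
    abundance = as.vector(m),
    stringsAsFactors = FALSE)
  quant <- quant[!is.na(quant$abundance), , drop = FALSE]
  paths <- c(
    predictions = file.path(dir, "predictions.tsv"),
    atlas = file.path(dir, "atlas.tsv"),
    biotypes = file.path(dir, "biotypes.tsv"),
    quant = file.path(dir, "protein_quant.tsv"),
    protein_map = file.path(dir, "protein_map.tsv"),
    mirna_changes = file.path(dir, "mirna_changes.tsv"),
    ct = file.path(dir, "ct.tsv"),
    truth = file.path(dir, "planted_truth.yaml"))
  .writeTsv(study@predictions, paths[["predictions"]])
  .writeTsv(study@atlas, paths[["atlas"]])
  .writeTsv(study@biotypes, paths[["biotypes"]])
  .writeTsv(quant, paths[["quant"]])
  .writeTsv(study@proteinMap, paths[["protein_map"]])
  .writeTsv(study@mirnaChanges, paths[["mirna_changes"]])
  .writeTsv(study@ct, paths[["ct"]])
  truth <- study@truth
  truth$consensusSites <- as.list(truth$consensusSites)
  truth$decoys <- as.list(truth$decoys)
  truth$inversePairs <- as.list(truth$inversePairs)
  truth$trueFolds <- as.list(truth$trueFolds)
  truth$trueEnrichments <- as.list(truth$trueEnrichments)
  yaml::write_yaml(truth, paths[["truth"]])
  invisible(paths)
}
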