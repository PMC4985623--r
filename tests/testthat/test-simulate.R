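test_that("configuration validation rejects out-of-range settings", {
  expect_error(simConfig(nGenes = 0), "positive")
  expect_error(simConfig(plantedConsensusFraction = 1.2), "\\[0, 1\\]")
  expect_error(simConfig(nReplicates = 1), ">= 2")
  expect_error(simConfig(mirnaFoldMap = c(100, 50)), "named")
  expect_error(simConfig(nGenes = 2, nMirnas = 2, nSites = 100),
               "nSites")
})

test_that("one seed makes every generated table reproducible", {
  cfg <- simConfig(seed = 7, nGenes = 60, nSites = 30)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(a@predictions, b@predictions)
  expect_identical(a@atlas, b@atlas)
  expect_identical(SummarizedExperiment::assay(a@proteome, "abundance"),
                   SummarizedExperiment::assay(b@proteome, "abundance"))
  expect_identical(a@ct, b@ct)
  expect_identical(plantedTruth(a), plantedTruth(b))
  # written outputs are byte-identical too
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- writeSimulatedStudy(a, d1)
  p2 <- writeSimulatedStudy(b, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("per-table sub-streams are independent", {
  cfg1 <- simConfig(seed = 5, nGenes = 60, nSites = 30)
  cfg2 <- simConfig(seed = 5, nGenes = 60, nSites = 30,
                    plantedEnrichmentMap = c("miR-96-5p" = 2))
  # changing the Ct-table settings must not perturb the predictions table
  expect_identical(simulatePredictions(cfg1)$predictions,
                   simulatePredictions(cfg2)$predictions)
})

test_that("planted consensus sites are recovered exactly", {
  cfg <- simConfig(seed = 11, nGenes = 500, nSites = 200,
                   plantedConsensusFraction = 0.3)
  sim <- simulatePredictions(cfg)
  cons <- consensusSites(predictedSites(sim$predictions))
  expect_equal(nrow(cons), 60)  # 200 * 0.3
  expect_setequal(
    paste(cons$mirna, cons$gene, cons$start, cons$end, cons$tools),
    paste(sim$truth$consensusSites$mirna, sim$truth$consensusSites$gene,
          sim$truth$consensusSites$start, sim$truth$consensusSites$end,
          sim$truth$consensusSites$tools))
  # decoys never surface: single-tool and non-overlapping two-tool loci
  decoyKey <- paste(sim$truth$decoys$mirna, sim$truth$decoys$gene)
  expect_length(intersect(paste(cons$mirna, cons$gene), decoyKey), 0)
  # zero planted fraction gives an empty consensus set
  cfg0 <- simConfig(seed = 11, nGenes = 100, nSites = 40,
                    plantedConsensusFraction = 0)
  sim0 <- simulatePredictions(cfg0)
  expect_equal(nrow(consensusSites(predictedSites(sim0$predictions))), 0)
  expect_equal(nrow(sim0$truth$consensusSites), 0)
})

test_that("noiseless proteome recovers planted folds exactly", {
  cfg <- simConfig(seed = 3, nGenes = 5, nSites = 4,
                   abundanceNoiseSd = 0,
                   plantedFoldMap = c(g00001 = 2.0, g00002 = 0.25))
  sim <- simulateProteome(cfg)
  de <- differentialAbundance(sim$proteome)
  de <- mapProteinsToGenes(de, sim$proteinMap)
  g1 <- de[de$gene == "g00001" & de$fraction == "whole", ]
  expect_equal(g1$fold_percent, 200)
  expect_true(is.na(g1$p_value))  # zero within-group variance
  g2 <- de[de$gene == "g00002" & de$fraction == "membrane", ]
  expect_equal(g2$fold_percent, 25)
})

test_that("fold estimates center on the planted value under noise", {
  # 400 iid planted genes stand in for repeated simulations
  n <- 400
  genes <- sprintf("g%05d", seq_len(n))
  cfg <- simConfig(seed = 21, nGenes = n, nSites = 10,
                   abundanceNoiseSd = 0.25,
                   plantedFoldMap = stats::setNames(rep(3.4, n), genes))
  sim <- simulateProteome(cfg)
  de <- differentialAbundance(sim$proteome)
  whole <- de[de$fraction == "whole", ]
  est <- whole$log2_fold
  # mean log2 fold-hat ~ N(log2 3.4, 2 * 0.25^2 / 4 / n)
  se <- sqrt(2 * 0.25^2 / 4 / n)
  expect_lt(abs(mean(est) - log2(3.4)), 4 * se)
})

test_that("null proteome holds the nominal type-I error", {
  cfg <- simConfig(seed = 42, nGenes = 1000, nSites = 10,
                   abundanceNoiseSd = 0.25)
  sim <- simulateProteome(cfg)
  de <- differentialAbundance(sim$proteome)
  whole <- de[de$fraction == "whole", ]
  rate <- mean(whole$p_value < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / nrow(whole))
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

test_that("Ct tables encode planted enrichments and dropout", {
  cfg <- simConfig(seed = 9, nGenes = 10, nSites = 5, ctNoiseSd = 0,
                   plantedEnrichmentMap = c(m4 = 4.0, mInf = Inf))
  sim <- simulateCtMatrix(cfg)
  ct <- sim$ct
  gap <- function(assay) {
    mean(ct$ct[ct$assay == assay & ct$sample == "capture"]) -
      mean(ct$ct[ct$assay == assay & ct$sample == "scrambled"])
  }
  expect_equal(gap("m4"), -2)  # -log2(4) cycles
  scrInf <- ct$ct[ct$assay == "mInf" & ct$sample == "scrambled"]
  expect_true(all(is.na(scrInf)))  # explicit missing marker, no sentinel
  capInf <- ct$ct[ct$assay == "mInf" & ct$sample == "capture"]
  expect_true(all(!is.na(capInf)))
  # estimator recovery at the planted 5.07-fold under noise
  est <- vapply(seq_len(200), function(i) {
    cfg2 <- simConfig(seed = 1000 + i, nGenes = 10, nSites = 5,
                      plantedEnrichmentMap = c(m = 5.07))
    mirnaFold(simulateCtMatrix(cfg2)$ct, "m")$fold
  }, numeric(1))
  se <- sqrt(2 * 0.3^2 / 3 / 200)
  expect_lt(abs(mean(log2(est)) - log2(5.07)), 4 * se)
})

test_that("planted truths are cross-stage consistent", {
  for (seed in c(2, 8)) {
    st <- simulateStudy(simConfig(seed = seed, nGenes = 150, nSites = 60))
    tr <- plantedTruth(st)
    consKey <- paste(tr$consensusSites$mirna, tr$consensusSites$gene)
    mirFold <- simConfigOf(st)@mirnaFoldMap
    for (i in seq_len(nrow(tr$inversePairs))) {
      m <- tr$inversePairs$mirna[i]
      g <- tr$inversePairs$gene[i]
      # every inverse pair references a planted consensus site
      expect_true(paste(m, g) %in% consKey)
      # and a planted fold opposite to its miRNA's change
      pf <- tr$trueFolds[[g]]
      if (mirFold[[m]] < 75) expect_gt(pf, 1.25) else expect_lt(pf, 0.75)
      # pair genes survive the expression and biotype filters
      expect_true(g %in% tr$expressedGenes)
      expect_true(g %in% tr$codingGenes)
    }
  }
})

test_that("pair discovery recovers planted pairs in the noiseless limit", {
  cfg <- simConfig(seed = 17, nGenes = 200, nSites = 80,
                   abundanceNoiseSd = 1e-9)
  st <- simulateStudy(cfg)
  tr <- plantedTruth(st)
  cons <- consensusSites(predictedSites(st@predictions))
  de <- differentialAbundance(st@proteome)
  de <- mapProteinsToGenes(de, st@proteinMap)
  pairs <- inversePairs(st@mirnaChanges, de, candidatesPerMirna(cons))
  expect_setequal(paste(pairs$mirna, pairs$gene, pairs$direction),
                  paste(tr$inversePairs$mirna, tr$inversePairs$gene,
                        tr$inversePairs$direction))
})
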