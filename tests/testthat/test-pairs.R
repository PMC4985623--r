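mirnaTab <- data.frame(
  mirna = c("miR-96", "miR-1", "miR-142"),
  fold_retina_percent = c(50, 550, 400),
  fold_photoreceptor_percent = c(60, 2000, 1000))

test_that("the inverse rule pairs opposite miRNA and protein changes", {
  de <- makeDe(
    list(protein = "pRac1", gene = "Rac1", fraction = "whole",
         fold = 339.9, p = 0.0008),
    list(protein = "pRac1", gene = "Rac1", fraction = "membrane",
         fold = 60.3, p = 0.04),
    list(protein = "pCtbp2", gene = "Ctbp2", fraction = "whole",
         fold = 53.8, p = 0.004))
  cand <- list("miR-96" = "Rac1", "miR-1" = "Ctbp2")
  pairs <- inversePairs(mirnaTab, de, cand)
  expect_equal(nrow(pairs), 2)
  rac1 <- pairs[pairs$gene == "Rac1", ]
  expect_equal(rac1$mirna, "miR-96")
  expect_equal(rac1$direction, "mirna_down_protein_up")
  expect_equal(rac1$fractions_supporting, "whole")
  # the significant membrane decrease conflicts but does not veto
  expect_equal(rac1$conflicting_fraction, "membrane")
  ctbp2 <- pairs[pairs$gene == "Ctbp2", ]
  expect_equal(ctbp2$direction, "mirna_up_protein_down")
  expect_equal(ctbp2$protein_fold_percent, 53.8)
})

test_that("same-direction and in-band changes never pair", {
  de <- makeDe(
    list(protein = "pA", gene = "gUp", fraction = "whole",
         fold = 300, p = 0.001),
    list(protein = "pB", gene = "gFlat", fraction = "whole",
         fold = 110, p = 0.001),
    list(protein = "pC", gene = "gNs", fraction = "whole",
         fold = 300, p = 0.2))
  # miR-1 is up; gUp moves the same way, gFlat is in-band, gNs not significant
  pairs <- inversePairs(mirnaTab, de,
                        list("miR-1" = c("gUp", "gFlat", "gNs")))
  expect_equal(nrow(pairs), 0)
  # an unchanged miRNA yields nothing even with a qualifying protein
  flat <- data.frame(mirna = "miR-x", fold_retina_percent = 100,
                     fold_photoreceptor_percent = NA)
  de2 <- makeDe(list(protein = "pA", gene = "gDown", fraction = "whole",
                     fold = 40, p = 0.001))
  expect_equal(nrow(inversePairs(flat, de2, list("miR-x" = "gDown"))), 0)
})

test_that("miRNAs absent from the fold table are skipped with a warning", {
  de <- makeDe(list(protein = "pA", gene = "g1", fraction = "whole",
                    fold = 300, p = 0.001))
  expect_warning(res <- inversePairs(mirnaTab, de,
                                     list("miR-miss" = "g1")),
                 "miR-miss")
  expect_equal(nrow(res), 0)
})

test_that("tightening thresholds never adds pairs", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 30
    de <- do.call(rbind, lapply(seq_len(n), function(i) {
      makeDe(list(protein = paste0("p", i), gene = paste0("g", i),
                  fraction = sample(c("whole", "membrane"), 1),
                  fold = stats::rlnorm(1, log(100), 0.9),
                  p = stats::runif(1, 0, 0.2)))
    }))
    cand <- list("miR-96" = paste0("g", 1:n), "miR-1" = paste0("g", 1:n))
    loose <- inversePairs(mirnaTab, de, cand,
                          pairThresholds(alpha = 0.1,
                                         mirnaBand = c(90, 110),
                                         proteinBand = c(90, 110)))
    tight <- inversePairs(mirnaTab, de, cand,
                          pairThresholds(alpha = 0.01,
                                         mirnaBand = c(75, 125),
                                         proteinBand = c(75, 125)))
    keyL <- paste(loose$mirna, loose$gene)
    keyT <- paste(tight$mirna, tight$gene)
    expect_true(all(keyT %in% keyL))
  }
})

test_that("threshold bands must straddle 100 percent", {
  expect_error(pairThresholds(mirnaBand = c(110, 120)), "straddle")
  expect_error(pairThresholds(proteinBand = c(50, 90)), "straddle")
})

test_that("co-target matrix is symmetric with set-size diagonal", {
  pairs <- data.frame(
    mirna = c("miR-96", "miR-96", "miR-182", "miR-182", "miR-1"),
    gene = c("g1", "g2", "g1", "g2", "g3"))
  m <- sharedTargets(pairs)
  expect_true(isSymmetric(m))
  expect_equal(m["miR-96", "miR-96"], 2)
  expect_equal(m["miR-96", "miR-182"], 2)
  expect_equal(m["miR-1", "miR-96"], 0)
  # brute-force cross-check on a random pair table
  set.seed(3)
  rp <- data.frame(mirna = sample(c("a", "b", "c"), 40, replace = TRUE),
                   gene = sample(paste0("g", 1:12), 40, replace = TRUE))
  mm <- sharedTargets(rp)
  for (i in rownames(mm)) {
    for (j in colnames(mm)) {
      expect_equal(mm[i, j],
                   length(intersect(unique(rp$gene[rp$mirna == i]),
                                    unique(rp$gene[rp$mirna == j]))))
    }
  }
})
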