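makeCt <- function(assay, capture, scrambled) {
  data.frame(assay = assay,
             sample = rep(c("capture", "scrambled"),
                          c(length(capture), length(scrambled))),
             replicate = c(seq_along(capture), seq_along(scrambled)),
             ct = c(capture, scrambled))
}

test_that("complementary stretch handles canonical and empty matches", {
  target <- randomDna(200)
  window <- substr(target, 90, 111)
  probe <- rcBase(window)
  expect_equal(longestComplementaryStretch(probe, target), 22)
  expect_equal(longestComplementaryStretch("AAAA", "AAAA"), 0)
  expect_error(longestComplementaryStretch("ACGU", "ACGT"), "non-ACGT")
  expect_error(longestComplementaryStretch("", "ACGT"), "non-empty")
})

test_that("complementary stretch matches the brute-force scan", {
  set.seed(19)
  for (rep in 1:20) {
    probe <- randomDna(18)
    target <- randomDna(250)
    expect_equal(longestComplementaryStretch(probe, target),
                 bruteStretch(probe, target))
  }
})

test_that("complementary stretch is symmetric in its arguments", {
  set.seed(29)
  for (rep in 1:10) {
    a <- randomDna(25)
    b <- randomDna(60)
    expect_equal(longestComplementaryStretch(a, b),
                 longestComplementaryStretch(b, a))
  }
})

test_that("off-target screen uses an inclusive 15-nt bound", {
  set.seed(4)
  probes <- Biostrings::readDNAStringSet(
    system.file("extdata", "capture_probes.fasta",
                package = "mircircuits"))
  c9 <- as.character(probes[[1]])
  # decoys with planted complementary stretches of 15, 16 and 18 nt
  mk <- function(len) {
    paste0(randomDna(40), rcBase(substr(c9, 1, len)), randomDna(40))
  }
  decoys <- c(ok15 = mk(15), bad16 = mk(16), bad18 = mk(18))
  res <- screenOfftargets(c9, decoys)
  expect_true(res$pass[res$transcript == "ok15"])
  expect_false(res$pass[res$transcript == "bad16"])
  expect_false(res$pass[res$transcript == "bad18"])
  expect_gte(res$stretch[res$transcript == "bad18"], 18)
})

test_that("comparative Ct mRNA fold follows the delta-delta-Ct rule", {
  flat <- rbind(makeCt("Rac1", c(25, 25), c(25, 25)),
                makeCt("Actb", c(20, 20), c(20, 20)))
  expect_equal(mrnaFold(flat, "Rac1", "Actb")$fold, 1)
  shifted <- rbind(makeCt("Rac1", c(23, 23), c(25, 25)),
                   makeCt("Actb", c(20, 20), c(20, 20)))
  expect_equal(mrnaFold(shifted, "Rac1", "Actb")$fold, 4)
  expect_equal(mrnaFold(shifted, "Rac1", normalizer = NULL)$fold, 4)
  dead <- rbind(makeCt("Rac1", c(23, 23), c(NA, NA)),
                makeCt("Actb", c(20, 20), c(20, 20)))
  res <- mrnaFold(dead, "Rac1", "Actb")
  expect_false(res$quantifiable)
  expect_true(is.na(res$fold))
  expect_error(mrnaFold(flat, "missing", "Actb"), "not found")
})

test_that("miRNA fold applies background filtering and n/a semantics", {
  eq <- makeCt("miR-x", c(30, 30, 30), c(30, 30, 30))
  expect_equal(mirnaFold(eq, "miR-x")$fold, 1)
  up <- makeCt("miR-x", c(28, 28), c(30, 30))
  expect_equal(mirnaFold(up, "miR-x")$fold, 4)
  # one of two scrambled replicates not amplified: fold kept, p absent
  oneDrop <- makeCt("miR-x", c(28, 28.4), c(31, NA))
  res <- mirnaFold(oneDrop, "miR-x")
  expect_false(is.na(res$fold))
  expect_true(is.na(res$p_value))
  expect_equal(res$n_scrambled_detected, 1)
  # scrambled fully censored: unquantifiable fold, capture flag retained
  allDrop <- makeCt("miR-x", c(28, 28, 29), c(NA, 39, 38.5))
  res2 <- mirnaFold(allDrop, "miR-x", detectionLimit = 37)
  expect_true(is.na(res2$fold))
  expect_true(res2$capture_detected)
  expect_equal(res2$n_scrambled_detected, 0)
  expect_error(mirnaFold(eq, "absent"), "not found")
})

test_that("folds are shift-invariant and antisymmetric under label swap", {
  set.seed(12)
  cap <- 27 + stats::rnorm(3, 0, 0.3)
  scr <- 30 + stats::rnorm(3, 0, 0.3)
  ct <- makeCt("m", cap, scr)
  base <- mirnaFold(ct, "m")
  shifted <- makeCt("m", cap + 2.5, scr + 2.5)
  expect_equal(mirnaFold(shifted, "m")$fold, base$fold, tolerance = 1e-12)
  swapped <- makeCt("m", scr, cap)
  expect_equal(mirnaFold(swapped, "m")$fold, 1 / base$fold,
               tolerance = 1e-12)
  # mRNA route too
  ctm <- rbind(makeCt("t", cap, scr), makeCt("Actb", c(20, 20), c(20, 20)))
  ctmShift <- rbind(makeCt("t", cap + 3, scr + 3),
                    makeCt("Actb", c(23, 23), c(23, 23)))
  expect_equal(mrnaFold(ctmShift, "t", "Actb")$fold,
               mrnaFold(ctm, "t", "Actb")$fold, tolerance = 1e-12)
})

test_that("shared-site folds sum with unquantifiable propagation", {
  res <- data.frame(assay = c("miR-96-5p", "miR-182-5p", "miR-151-3p"),
                    fold = c(5.07, 3.63, NA))
  comb <- combineSharedSite(res, list(
    site = c("miR-96-5p", "miR-182-5p"),
    solo = "miR-96-5p",
    broken = c("miR-96-5p", "miR-151-3p")))
  expect_equal(comb$fold[comb$group == "site"], 8.70)
  expect_equal(comb$fold[comb$group == "solo"], 5.07)
  expect_true(is.na(comb$fold[comb$group == "broken"]))
  expect_false(comb$quantifiable[comb$group == "broken"])
  # permutation invariance
  comb2 <- combineSharedSite(res, list(site = c("miR-182-5p", "miR-96-5p")))
  expect_equal(comb2$fold, comb$fold[comb$group == "site"])
  expect_error(combineSharedSite(res, list(empty = character(0))), "empty")
  expect_error(combineSharedSite(res, list(g = "miR-999")), "unquantified")
})

test_that("classification against predictions reproduces the panel parts", {
  panel <- read.delim(system.file("extdata", "rac1_mircatch_panel.tsv",
                                  package = "mircircuits"))
  results <- data.frame(assay = panel$mirna, fold = panel$fold,
                        p_value = panel$p_value,
                        n_capture_detected = 2, n_scrambled_detected = 2,
                        capture_detected = TRUE)
  preds <- panel[panel$part == "a", c("mirna", "n_sites", "regions")]
  preds$region <- preds$regions
  cls <- classifyMirnas(results, preds, enrichCut = 1.5)
  expect_setequal(cls$mirna[cls$part == "a"],
                  panel$mirna[panel$part == "a"])
  expect_setequal(cls$mirna[cls$part == "b"],
                  panel$mirna[panel$part == "b"])
  expect_equal(cls$regions[cls$mirna == "miR-103-3p"], "three_prime_utr")
  expect_equal(cls$n_sites[cls$mirna == "miR-96-5p"], 3)
  # sorted by fold descending, unquantifiable entries last, per part
  for (p in c("a", "b")) {
    f <- cls$fold[cls$part == p]
    quantified <- f[!is.na(f)]
    expect_true(all(diff(quantified) <= 0))
    expect_true(all(which(is.na(f)) > length(quantified)))
  }
  # merged duplicate site intervals are counted once across sources
  twoSrc <- data.frame(
    mirna = "miR-z", source = c("utr_tool", "full_cdna_tool"),
    region = "three_prime_utr", start = c(10, 10), end = c(25, 25))
  resZ <- data.frame(assay = "miR-z", fold = 3, p_value = 0.01,
                     n_capture_detected = 2, n_scrambled_detected = 2,
                     capture_detected = TRUE)
  clsZ <- classifyMirnas(resZ, twoSrc)
  expect_equal(clsZ$n_sites, 1)
})
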