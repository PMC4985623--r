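test_that("prediction reader validates the site dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("tool\tmirna\tgene\ttranscript\tregion\tstart\tend\tscore",
             path)
  expect_length(readPredictions(path), 0)

  writeLines(c("tool\tmirna\tgene\ttranscript\tregion\tstart\tend\tscore",
               "A\tmiR-1\tg1\tt1\tthree_prime_utr\t50\t40\t0.5"), path)
  expect_error(readPredictions(path), "row")

  writeLines(c("mirna\tgene\ttranscript\tregion\tstart\tend",
               "miR-1\tg1\tt1\tthree_prime_utr\t10\t20"), path)
  expect_error(readPredictions(path), "tool")
  expect_length(readPredictions(path, tool = "A"), 1)
})

test_that("site lengths outside 6-30 nt warn but are kept", {
  df <- data.frame(tool = "A", mirna = "m", gene = "g", transcript = "t",
                   region = "cds", start = c(1, 100), end = c(3, 110))
  expect_warning(gr <- predictedSites(df), "6-30")
  expect_length(gr, 2)
})

test_that("two overlapping tools merge into one consensus site", {
  df <- data.frame(
    tool = c("A", "B"), mirna = "miR-1", gene = "g1", transcript = "t1",
    region = "three_prime_utr", start = c(100, 110), end = c(120, 130))
  res <- consensusSites(predictedSites(df))
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 100)
  expect_equal(res$end, 130)
  expect_equal(res$tools, "A,B")
  expect_equal(res$intersectionStart, 110)
  expect_equal(res$intersectionEnd, 120)
})

test_that("a single tool can never reach consensus", {
  df <- data.frame(tool = "A", mirna = "miR-1", gene = "g1",
                   transcript = "t1", region = "cds",
                   start = c(10, 12, 30), end = c(20, 22, 40))
  expect_equal(nrow(consensusSites(predictedSites(df))), 0)
  expect_error(consensusSites(predictedSites(df), minTools = 0), "minTools")
})

test_that("consensus grouping matches the pairwise-intersection oracle", {
  set.seed(41)
  for (rep in 1:25) {
    df <- randomSiteTable(sample(10:60, 1))
    res <- consensusSites(predictedSites(df))
    oracle <- bruteConsensus(df)
    expect_equal(siteKey(res), siteKey(oracle))
  }
})

test_that("consensus is invariant under row and tool-label permutation", {
  set.seed(13)
  df <- randomSiteTable(40)
  res <- consensusSites(predictedSites(df))
  shuffled <- df[sample.int(nrow(df)), , drop = FALSE]
  expect_equal(siteKey(consensusSites(predictedSites(shuffled))),
               siteKey(res))
  relabel <- c(tool1 = "toolX", tool2 = "toolY", tool3 = "toolZ")
  df2 <- df
  df2$tool <- unname(relabel[df$tool])
  res2 <- consensusSites(predictedSites(df2))
  expect_equal(nrow(res2), nrow(res))
  expect_equal(res2[, c("start", "end")], res[, c("start", "end")])
})

test_that("raising minTools never increases the consensus set", {
  set.seed(99)
  for (rep in 1:10) {
    gr <- predictedSites(randomSiteTable(50))
    sizes <- vapply(1:4, function(k) nrow(consensusSites(gr, minTools = k)),
                    integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("candidate gene sets use set semantics", {
  expect_length(candidatesPerMirna(consensusSites(predictedSites(
    data.frame(tool = character(0), mirna = character(0),
               gene = character(0), transcript = character(0),
               region = character(0), start = integer(0),
               end = integer(0))))), 0)
  df <- data.frame(
    tool = rep(c("A", "B"), 3), mirna = "miR-1", gene = "g1",
    transcript = paste0("t", rep(1:3, each = 2)),
    region = "three_prime_utr",
    start = rep(c(10, 12), 3), end = rep(c(20, 22), 3))
  cand <- candidatesPerMirna(consensusSites(predictedSites(df)))
  expect_equal(cand, list("miR-1" = "g1"))
})

test_that("stage summaries compute Sum and Unique rows", {
  sets <- list(
    stageA = list(m1 = c("a", "b", "c"), m2 = c("b", "c", "d")),
    stageB = list(m1 = c("a", "b"), m2 = "d"))
  res <- summarizeCounts(sets)
  expect_equal(res["Sum", "stageA"], 6)
  expect_equal(res["Unique", "stageA"], 4)
  expect_equal(res["Sum", "stageB"], 3)
  expect_equal(res["Unique", "stageB"], 3)
  expect_true(all(res["Unique", ] <= res["Sum", ]))

  counts <- summarizeCounts(list(sites = c(m1 = 10, m2 = 20)))
  expect_equal(counts["Sum", "sites"], 30)
  expect_true(is.na(counts["Unique", "sites"]))

  none <- summarizeCounts(list(stage = list()))
  expect_equal(none["Sum", "stage"], 0)
  expect_equal(none["Unique", "stage"], 0)
})
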