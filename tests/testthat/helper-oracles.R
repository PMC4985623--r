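# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately share no code with
# the implementations they check.

# Consensus grouping by exhaustive pairwise intersection + BFS over the
# overlap graph, per (miRNA, transcript).
bruteConsensus <- function(df, minTools = 2, minOverlap = 1) {
  out <- list()
  for (key in unique(paste(df$mirna, df$transcript, sep = "\r"))) {
    d <- df[paste(df$mirna, df$transcript, sep = "\r") == key, ,
            drop = FALSE]
    n <- nrow(d)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        ov <- min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]) + 1
        adj[i, j] <- ov >= minOverlap
      }
    }
    seen <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (seen[i]) next
      comp <- i
      queue <- i
      seen[i] <- TRUE
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & !seen)
        seen[nb] <- TRUE
        comp <- c(comp, nb)
        queue <- c(queue, nb)
      }
      tools <- sort(unique(d$tool[comp]))
      if (length(tools) >= minTools) {
        out[[length(out) + 1L]] <- data.frame(
          mirna = d$mirna[comp[1]], transcript = d$transcript[comp[1]],
          start = min(d$start[comp]), end = max(d$end[comp]),
          tools = paste(tools, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      tools = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Random site table generator for oracle comparisons.
randomSiteTable <- function(n, nMirnas = 2, nTranscripts = 4, nTools = 3,
                            maxPos = 120) {
  tx <- sprintf("tx%02d", seq_len(nTranscripts))
  start <- sample.int(maxPos, n, replace = TRUE)
  width <- sample(6:14, n, replace = TRUE)
  data.frame(
    tool = sample(paste0("tool", seq_len(nTools)), n, replace = TRUE),
    mirna = sample(paste0("miR-", seq_len(nMirnas)), n, replace = TRUE),
    gene = "g", transcript = sample(tx, n, replace = TRUE),
    region = "three_prime_utr",
    start = start, end = start + width - 1L,
    stringsAsFactors = FALSE)
}

siteKey <- function(d) {
  sort(paste(d$mirna, d$transcript, d$start, d$end, d$tools))
}

# Exhaustive hypergeometric upper tail by enumerating every possible
# foreground draw from the background.
enumHyperP <- function(N, m, nF, k) {
  draws <- utils::combn(N, nF)
  marked <- seq_len(m)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Reverse complement without Biostrings.
rcBase <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Longest complementary stretch by checking every probe substring for an
# exact reverse-complement occurrence in the target.
bruteStretch <- function(probe, target) {
  np <- nchar(probe)
  best <- 0L
  for (i in seq_len(np)) {
    for (j in i:np) {
      if (j - i + 1 <= best) next
      sub <- substr(probe, i, j)
      if (grepl(rcBase(sub), target, fixed = TRUE)) {
        best <- j - i + 1L
      }
    }
  }
  best
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small deterministic differential table for pair-discovery tests.
makeDe <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r$protein, gene = r$gene, fraction = r$fraction,
               fold_percent = r$fold, log2_fold = log2(r$fold / 100),
               p_value = r$p, note = "", representative = TRUE,
               stringsAsFactors = FALSE)
  }))
}
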