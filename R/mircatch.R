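#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet
NULL

.checkDna <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    stop(what, " must be a single non-empty DNA string")
  }
  s <- toupper(x)
  if (grepl("[^ACGT]", s)) {
    stop(what, " contains non-ACGT character(s)")
  }
  s
}

#' Longest perfect antiparallel complementary stretch
#'
#' Length of the longest contiguous run over which the probe, read
#' antiparallel, is perfectly Watson-Crick complementary to a substring of
#' the target (0 if none). Equivalently, the longest common substring of
#' the probe's reverse complement and the target; computed by scanning
#' match runs along every alignment diagonal. Used to vet capture
#' oligonucleotides against off-target transcripts.
#'
#' @param probe DNA string (5'->3').
#' @param target DNA string (5'->3').
#' @return integer length in nucleotides.
#' @export
longestComplementaryStretch <- function(probe, target) {
  p <- .checkDna(probe, "probe")
  t <- .checkDna(target, "target")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
  a <- utf8ToInt(rc)
  b <- utf8ToInt(t)
  na <- length(a)
  nb <- length(b)
  best <- 0L
  for (off in seq.int(-(na - 1L), nb - 1L)) {
    js <- seq.int(max(1L, 1L - off), min(na, nb - off))
    m <- a[js] == b[js + off]
    if (!any(m)) next
    r <- rle(m)
    best <- max(best, max(r$lengths[r$values]))
  }
  as.integer(best)
}

#' Screen a capture probe against off-target transcripts
#'
#' A transcript fails the screen iff its longest perfect antiparallel
#' complementary stretch with the probe exceeds `maxStretch` nucleotides
#' (a stretch of exactly `maxStretch` passes). The transcript set should
#' exclude the probe's intended target.
#'
#' @param probe DNA string (5'->3').
#' @param transcripts named character vector or
#'   [Biostrings::DNAStringSet] of transcript sequences.
#' @param maxStretch inclusive upper bound in nucleotides (default 15).
#' @return data.frame with columns `transcript`, `stretch`, `pass`.
#' @export
screenOfftargets <- function(probe, transcripts, maxStretch = 15) {
  if (methods::is(transcripts, "DNAStringSet")) {
    transcripts <- stats::setNames(as.character(transcripts),
                                   names(transcripts))
  }
  if (is.null(names(transcripts)) || any(!nzchar(names(transcripts)))) {
    stop("transcripts must be named")
  }
  stretch <- vapply(transcripts,
                    function(s) longestComplementaryStretch(probe, s),
                    integer(1))
  data.frame(transcript = names(transcripts),
             stretch = as.integer(stretch),
             pass = stretch <= maxStretch,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a qPCR Ct table
#'
#' Expects columns `assay`, `sample` (capture or scrambled), `replicate`,
#' `ct`. A not-amplified assay is recorded as the explicit missing marker
#' `NA` in the `ct` column, never as a sentinel cycle number.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readCtTable <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("assay", "sample", "replicate", "ct"),
                  paste0("Ct file ", path))
  df$ct <- suppressWarnings(as.numeric(df$ct))
  if (any(df$ct <= 0, na.rm = TRUE)) {
    stop("Ct values must be positive when present")
  }
  if (!all(df$sample %in% c("capture", "scrambled"))) {
    stop("sample must be 'capture' or 'scrambled'")
  }
  df
}

.armCt <- function(ct, assay, sample) {
  v <- ct$ct[ct$assay == assay & ct$sample == sample]
  v[!is.na(v)]
}

#' Target mRNA enrichment by the comparative Ct method
#'
#' Computes the capture/scrambled fold of a target mRNA. With a normalizer
#' assay (the default usage), fold = 2^-ddCt where dCt = mean Ct(target) -
#' mean Ct(normalizer) per sample and ddCt = dCt(capture) -
#' dCt(scrambled). With `normalizer = NULL` the raw comparison
#' 2^(mean Ct scrambled - mean Ct capture) of the target alone is used.
#' If any required assay has no amplified replicate in a required sample,
#' the fold is unquantifiable.
#'
#' @param ct data.frame from [readCtTable()].
#' @param target target mRNA assay identifier.
#' @param normalizer normalizer assay identifier (e.g. a housekeeping
#'   mRNA), or NULL for a normalizer-free comparison.
#' @return one-row data.frame: `target`, `normalizer`, `fold`,
#'   `quantifiable`.
#' @export
mrnaFold <- function(ct, target, normalizer = "Actb") {
  need <- c(target, normalizer)
  absent <- setdiff(need, unique(ct$assay))
  if (length(absent) > 0) {
    stop("assay(s) not found in Ct table: ", paste(absent, collapse = ", "))
  }
  arms <- expand.grid(assay = need, sample = c("capture", "scrambled"),
                      stringsAsFactors = FALSE)
  means <- mapply(function(a, s) {
    v <- .armCt(ct, a, s)
    if (length(v) == 0) NA_real_ else mean(v)
  }, arms$assay, arms$sample)
  if (any(is.na(means))) {
    return(data.frame(target = target,
                      normalizer = if (is.null(normalizer)) NA_character_
                      else normalizer,
                      fold = NA_real_, quantifiable = FALSE,
                      stringsAsFactors = FALSE))
  }
  mn <- function(a, s) means[arms$assay == a & arms$sample == s]
  if (is.null(normalizer)) {
    fold <- 2^(mn(target, "scrambled") - mn(target, "capture"))
  } else {
    ddct <- (mn(target, "capture") - mn(normalizer, "capture")) -
      (mn(target, "scrambled") - mn(normalizer, "scrambled"))
    fold <- 2^(-ddct)
  }
  data.frame(target = target,
             normalizer = if (is.null(normalizer)) NA_character_
             else normalizer,
             fold = as.numeric(fold), quantifiable = TRUE,
             stringsAsFactors = FALSE)
}

#' Normalizer-free miRNA enrichment with censoring semantics
#'
#' Capture and scrambled arms of a miRNA assay are compared on
#' background-filtered raw Ct values: replicates at or beyond
#' `detectionLimit` cycles, or recorded as not amplified, count as not
#' detected. The fold is 2^(mean Ct scrambled - mean Ct capture) over
#' detected replicates. If no scrambled replicate is detected the fold is
#' unquantifiable (the capture-detected flag is retained, since capture
#' signal over an undetectable background is itself evidence of
#' enrichment); the p-value (two-sided two-sample t-test on detected Ct
#' values, Welch by default) is computed only when each arm has at least
#' two detected replicates.
#'
#' @param ct data.frame from [readCtTable()].
#' @param assay miRNA assay identifier (must be present in `ct`).
#' @param detectionLimit background-filter Ct bound in cycles (default 37).
#' @param test `"welch"` (default) or `"pooled"` variance t-test.
#' @return one-row data.frame: `assay`, `fold`, `p_value`,
#'   `n_capture_detected`, `n_scrambled_detected`, `capture_detected`.
#' @export
mirnaFold <- function(ct, assay, detectionLimit = 37,
                      test = c("welch", "pooled")) {
  test <- match.arg(test)
  if (!assay %in% ct$assay) {
    stop("assay not found in Ct table: ", assay)
  }
  detect <- function(sample) {
    v <- ct$ct[ct$assay == assay & ct$sample == sample]
    v <- v[!is.na(v) & v < detectionLimit]
    v
  }
  cap <- detect("capture")
  scr <- detect("scrambled")
  fold <- if (length(scr) == 0 || length(cap) == 0) {
    NA_real_
  } else {
    2^(mean(scr) - mean(cap))
  }
  p <- if (length(cap) >= 2 && length(scr) >= 2) {
    # degenerate (essentially constant) data leaves the test undefined
    tryCatch(stats::t.test(cap, scr,
                           var.equal = (test == "pooled"))$p.value,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  data.frame(assay = assay, fold = fold, p_value = p,
             n_capture_detected = length(cap),
             n_scrambled_detected = length(scr),
             capture_detected = length(cap) > 0,
             stringsAsFactors = FALSE)
}

#' Enrichment of all miRNA assays in a Ct table
#'
#' Convenience wrapper applying [mirnaFold()] to each assay.
#'
#' @inheritParams mirnaFold
#' @param assays assays to quantify (default: all in `ct`).
#' @return data.frame with one row per assay.
#' @export
mirnaFoldTable <- function(ct, assays = unique(ct$assay),
                           detectionLimit = 37,
                           test = c("welch", "pooled")) {
  test <- match.arg(test)
  res <- do.call(rbind, lapply(assays, function(a) {
    mirnaFold(ct, a, detectionLimit = detectionLimit, test = test)
  }))
  rownames(res) <- NULL
  res
}

#' Combined enrichment of miRNAs sharing one target site
#'
#' miRNAs binding the same conserved site compete for it; their individual
#' capture/scrambled folds are summed to reflect combined usage of the
#' shared site. A group with any unquantifiable member is itself marked
#' unquantifiable; an empty group is an error.
#'
#' @param results data.frame from [mirnaFoldTable()] (or rbind of
#'   [mirnaFold()] rows).
#' @param groups named list, site-group label -> character vector of
#'   member miRNA assays.
#' @return data.frame: `group`, `members`, `fold`, `quantifiable`.
#' @examples
#' res <- data.frame(assay = c("miR-96-5p", "miR-182-5p"),
#'                   fold = c(5.07, 3.63))
#' combineSharedSite(res, list(`miR-96/182` = res$assay))  # 8.70
#' @export
combineSharedSite <- function(results, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    if (length(members) == 0) {
      stop("empty site group: ", g)
    }
    miss <- setdiff(members, results$assay)
    if (length(miss) > 0) {
      stop("group '", g, "' references unquantified assay(s): ",
           paste(miss, collapse = ", "))
    }
    folds <- results$fold[match(members, results$assay)]
    ok <- !any(is.na(folds))
    data.frame(group = g, members = paste(members, collapse = ","),
               fold = if (ok) sum(folds) else NA_real_,
               quantifiable = ok, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Merge per-source site predictions for one target transcript into one
# record per miRNA: site counts are summed after de-duplicating identical
# intervals (when explicit coordinates are given), regions are unioned.
.mergePredictions <- function(predictions) {
  .requireColumns(predictions, c("mirna"), "site predictions")
  hasCoords <- all(c("start", "end") %in% names(predictions))
  hasCounts <- "n_sites" %in% names(predictions)
  if (!hasCoords && !hasCounts) {
    stop("site predictions need either start/end columns or n_sites")
  }
  rows <- lapply(split(predictions, predictions$mirna), function(d) {
    if (hasCoords) {
      key <- paste(d$region, d$start, d$end)
      n <- length(unique(key))
    } else {
      n <- sum(as.numeric(d$n_sites))
    }
    regions <- if ("region" %in% names(d)) {
      sort(unique(unlist(strsplit(as.character(d$region), ","))))
    } else {
      character(0)
    }
    data.frame(mirna = d$mirna[1], n_sites = n,
               regions = paste(regions, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Classify captured miRNAs against in-silico predictions
#'
#' Cross-tabulates miR-CATCH enrichment results with merged target-site
#' predictions for the captured transcript. A miRNA counts as enriched
#' when its fold reaches `enrichCut`, or when the fold is unquantifiable
#' but capture signal was detected (no scrambled amplification is itself
#' evidence of enrichment). Part "a" holds miRNAs both enriched and
#' predicted (annotated with merged site counts and regions); part "b"
#' holds miRNAs enriched but not predicted. Each part is sorted by fold
#' descending with unquantifiable entries last.
#'
#' @param results data.frame from [mirnaFoldTable()].
#' @param predictions data.frame of per-source site predictions for the
#'   captured transcript: column `mirna` plus either explicit site rows
#'   (`region`, `start`, `end`; identical intervals are de-duplicated
#'   across sources) or per-source counts (`n_sites`, summed).
#' @param enrichCut fold threshold for calling a miRNA enriched
#'   (default 1.5).
#' @return data.frame: `mirna`, `fold`, `p_value`, `n_sites`, `regions`,
#'   `part` ("a" or "b").
#' @export
classifyMirnas <- function(results, predictions, enrichCut = 1.5) {
  merged <- if (nrow(predictions) > 0) {
    .mergePredictions(predictions)
  } else {
    data.frame(mirna = character(0), n_sites = numeric(0),
               regions = character(0), stringsAsFactors = FALSE)
  }
  enriched <- (!is.na(results$fold) & results$fold >= enrichCut) |
    (is.na(results$fold) & results$capture_detected)
  r <- results[enriched, , drop = FALSE]
  predicted <- r$assay %in% merged$mirna
  mi <- match(r$assay, merged$mirna)
  res <- data.frame(
    mirna = r$assay,
    fold = r$fold,
    p_value = r$p_value,
    n_sites = ifelse(predicted, merged$n_sites[mi], NA_real_),
    regions = ifelse(predicted, merged$regions[mi], NA_character_),
    part = ifelse(predicted, "a", "b"),
    stringsAsFactors = FALSE)
  res <- res[order(res$part, is.na(res$fold), -ifelse(is.na(res$fold), 0,
                                                      res$fold)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
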