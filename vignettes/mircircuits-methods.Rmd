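---
title: "Methods: discovering miRNA regulatory circuits from multi-omic data"
author: "mircircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering miRNA regulatory circuits from multi-omic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircircuits)
```

## The problem

Retinal degeneration models show reproducible dysregulation of a small set
of miRNAs: the sensory-organ-specific miR-183/96/182 cluster falls to
roughly half of wild-type levels while miR-1, miR-133 and miR-142 rise
4- to 5-fold. Because miRNAs act by repressing translation, their target
proteins should move in the *opposite* direction. This package implements
the desk half of that discovery loop: it intersects in-silico target-site
predictions with retinal expression, tests label-free proteomic abundance
changes between mutant and wild-type retinas, and pairs dysregulated
miRNAs with inversely changed proteins. Two companion analyses quantify a
miRNA pulldown (miR-CATCH) experiment by comparative Ct, and annotate a
protein-interaction network with expression and regulation calls.

Because the raw mass-spectrometry and prediction data behind the original
counts are not publicly deposited, the package ships a synthetic-data
generator that emulates every input with *planted truths*, so each stage
can be validated end-to-end without downloads.

## Consensus target calling

Per-tool predictions are transcript-coordinate intervals. Internally they
are held as a `GRanges` with the transcript as the sequence name and
1-based closed intervals, the native IRanges convention — this matches the
dialect the prediction tools emit and gives exact interval arithmetic
without conversion.

A *consensus site* is a connected component of the positional-overlap
graph among predictions sharing a (miRNA, transcript), supported by at
least `minTools = 2` distinct tools. Design choices that were genuinely
open:

* **Overlap width.** "Same location" is interpreted as an intersection of
  at least 1 nt; the `minOverlap` parameter exposes stricter settings.
* **Reported interval.** The union (span) of supporting intervals is
  reported, preserving all evidence; the intersection is retained as
  `intersectionStart`/`intersectionEnd` and may be empty for chained
  overlaps (recorded as `NA`, never a zero-width interval).
* **Site length.** Tool-reported blocks typically span 6–30 nt; lengths
  outside that range warn rather than reject, since the bound describes
  tool behaviour, not a biological rule.
* **Two-column funnel.** Genes predicted by ≥2 tools at *non-overlapping*
  positions count for the "≥2 methods" stage but are excluded from the
  overlapping-sites stage; the synthetic generator plants both kinds of
  decoy to keep this distinction testable.

`summarizeCounts()` renders the per-miRNA funnel with `Sum` (column
totals) and `Unique` (distinct genes in the union across miRNAs) rows.
When only printed per-miRNA counts are available, `Sum` is computable but
`Unique` is not (it needs gene identities) and is reported `NA`; the
`Unique` semantics are validated on synthetic data, where identities are
known.

## Expression filtering

The atlas pools FPKM and RPKM values on one scale without rescaling —
both are per-kilobase-per-million normalizations and the source libraries
are treated as interchangeable. A gene is *expressed* when its maximum
over datasets is ≥ 0.5 FPKM/RPKM (inclusive). Percentages reported from
counts use half-away-from-zero rounding, which reproduces printed
coverage figures such as 9.7% (1237/12758) exactly from their ratios.

## Differential protein abundance

Per protein and fraction (whole retina and membrane-enriched extracts are
tested independently, never pooled), the fold is
`100 * mean(mutant) / mean(wt)` percent of wild type, and significance is
a one-way two-group analysis of variance — algebraically the two-sided
pooled-variance t-test, which the test suite verifies against `aov()` to
1e-10. Three deliberate conventions:

* Whether the original statistics ran on raw or transformed abundances is
  not documented; the default tests raw values and a `transform = "log2"`
  option is provided. The fold is always computed from raw means.
* Zero within-group variance in both groups leaves the test undefined:
  the p-value is reported missing, never 0 or 1, to avoid fabricating
  significance in degenerate (e.g. noiseless) data.
* No multiple-testing correction is applied at this stage — downstream
  filters use raw p < 0.05 by design. Benjamini–Hochberg q-values appear
  only in the over-representation module.

Protein-to-gene mapping is many-to-one; within each (gene, fraction) the
record with the smallest p-value is flagged as the representative used by
per-gene analyses.

## Inverse-pair discovery

A candidate pair (miRNA, gene) requires: the gene among the miRNA's
consensus candidates; the miRNA's retinal fold outside the 75–125%
unchanged band (alterations in excess of ±25%); and the protein fold
significant (p < 0.05) and outside its band in the opposite direction in
at least one fraction. A significant *same-direction* protein change in
the other fraction — which occurs in real data when a membrane fraction
loses a protein that whole-retina extracts gain — does not veto the pair
but is flagged `conflicting_fraction`, because fraction-specific
artefacts (e.g. loss of outer-segment membranes) can mask genuine
regulation. The retina fold column is primary; the photoreceptor column
is annotation only, since targets are discovered retina-wide.

## Pathway over-representation

Up- and down-regulated sets use strict fold bounds (> 2.0-fold,
< 0.5-fold; a fold of exactly 2 is excluded) with raw p < 0.05. Each gene
set is intersected with the background (all genes mapped from identified
proteins) to its *effective* size; the p-value is the upper-tail
hypergeometric probability of at least the observed overlap. Sets with
overlap ≥ 2 form the tested family: q-values are Benjamini–Hochberg
across that family first, then the p < 0.05 report filter applies.
Whether the original q-values were computed per source database or pooled
is not documented; this implementation pools across databases (the
`source` tag is carried per set for per-database analyses). Bar-chart
columns clamp −log10 p and q at 3.

## miR-CATCH quantification

* **Probe vetting.** `longestComplementaryStretch()` finds the longest
  contiguous run over which a probe, read antiparallel, is perfectly
  Watson–Crick complementary to a target substring (the longest common
  substring of the probe's reverse complement and the target, scanned by
  alignment diagonal). Off-targets fail at stretches above 15 nt
  (inclusive bound: exactly 15 passes).
* **mRNA enrichment.** Comparative Ct with a housekeeping normalizer:
  fold = 2^−ΔΔCt. Whether the published ~50-fold capture enrichment was
  normalizer-corrected is ambiguous, so a normalizer-free mode
  (`normalizer = NULL`) is also provided; on the synthetic generator both
  agree because the normalizer is planted flat.
* **miRNA enrichment.** Capture and scrambled samples have different RNA
  compositions, so no normalizer is used: folds compare background-
  filtered raw Ct means. The background filter bound is not published;
  the default is Ct 37, configurable. Censoring semantics follow the
  panel conventions: no detected scrambled replicate makes the fold
  unquantifiable (but the capture-detected flag is kept and such miRNAs
  still count as enriched — capture signal over an undetectable
  background is evidence, not absence); the t-test (Welch by default,
  pooled optional) requires ≥2 detected replicates per arm.
* **Shared sites.** miRNAs binding one conserved site have their folds
  summed to reflect combined site usage.
* **Classification.** The enrichment call threshold is not published;
  the default `enrichCut = 1.5` sits below the smallest quantified panel
  fold reported with a p-value trend (1.65) and is configurable.
  Predictions from 3′UTR-scope and full-cDNA-scope tools are merged per
  miRNA (identical intervals de-duplicated, regions unioned) before the
  enriched-and-predicted ("part a") versus enriched-only ("part b")
  split.

## Interactome overlay

Annotation only — edge semantics are untouched. Tiers follow the log2
expression scale with the cutoff at −1 (0.5 linear); regulation calls
reuse the proteomics thresholds. Output includes a GML rendering for
standard viewers (logical flags become 0/1, as GML has no boolean type).

## The synthetic generator and what it does (not) show

One integer seed drives every table through fixed per-table sub-streams,
so regenerating one table never perturbs another and identical
configurations are byte-identical. Defaults encode the emulated study:
4 replicates per group and fraction, log2-normal abundance noise with
sd 0.25 (multiplicative error typical of label-free MS), additive
Gaussian Ct noise with sd 0.3 cycles, triplicate qPCR, the six miRNAs at
their published fold-changes, and a ~50-fold planted mRNA capture
enrichment. Not-amplified assays are recorded as an explicit `NA`
marker, never a sentinel Ct.

Planted truths are constructed to be mutually consistent: every planted
inverse pair references a planted consensus site and a protein fold
opposite to its miRNA's change, and pair genes are forced expressed and
protein-coding so they survive the funnel. Because the same
multiplicative noise law applies to both groups, the ratio of group
expectations equals the planted fold exactly.

Two numerical edges deserve note. First, at exactly zero abundance noise
the within-group variance vanishes and the significance test is
undefined by design (missing p), so "noiseless-limit" recovery is
exercised at a negligible sd of 1e-9, where recovery is exact and
deterministic. Second, the generator does not emulate tool-specific
score distributions, peptide-level missingness, batch structure, or
compositional coupling between fractions — passing tests demonstrate the
correctness of the pipeline's logic and statistics under the stated
noise model, not robustness to every artefact of real LC-MS/MS or panel
qPCR data.

## Problem sizes used in validation

The shipped validation runs use synthetic universes of 150–500 genes,
200 site loci (30% planted consensus), 1000 null proteins for the
type-I-error measurement, and 200 Monte-Carlo replicates for the qPCR
estimator recoveries; oracle-equivalence checks run 100 random fixtures
of up to 200 sites against an exhaustive pairwise-intersection oracle,
exact hypergeometric enumeration on backgrounds of ≤ 20 genes, and 100
random probe/target pairs against a brute-force substring scan. These
sizes give stable statistics while keeping the whole suite quick on a
laptop.

## Worked example

```{r example}
cfg <- simConfig(seed = 7, nGenes = 150, nSites = 60)
study <- simulateStudy(cfg)
study

cons <- consensusSites(predictedSites(study@predictions))
de <- suppressWarnings(
  mapProteinsToGenes(differentialAbundance(study@proteome),
                     study@proteinMap))
pairs <- inversePairs(study@mirnaChanges, de, candidatesPerMirna(cons))
head(pairs)
sharedTargets(pairs)
```

## Known limitations

* The `Unique` rows of the published funnel cannot be re-derived from
  printed per-miRNA counts; they are validated on synthetic data only.
* The published per-miRNA pair counts ("23, 10, 6, 18, 35" against six
  miRNAs) are internally inconsistent in the source material and are not
  reproduced.
* Headline biological counts (133 candidate pairs, 811 differential
  proteins) depend on unreleased raw data and are out of desk-scale
  reach; the package validates the *procedure* on planted truths and the
  *arithmetic* on the published summary tables.
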