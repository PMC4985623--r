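# mircircuits

Discovery of miRNA regulatory circuits from multi-omic retina data.

## What this is for

In inherited retinal degeneration models, a handful of miRNAs change
reproducibly: the sensory-organ-specific miR-183/96/182 cluster drops to
~50% of wild-type levels while miR-1/133 and miR-142 rise several-fold.
Since miRNAs repress translation, their genuine targets should show
*inverse* protein changes. `mircircuits` implements the computational
arm of that discovery strategy for anyone integrating target
predictions, transcriptome atlases, label-free proteomics and pulldown
qPCR:

1. **Consensus target calling** — merge per-tool target-site predictions,
   keeping sites supported by ≥ 2 tools at overlapping transcript
   positions (connected components of the interval-overlap graph), and
   tabulate the per-miRNA candidate funnel with `Sum`/`Unique` rows.
2. **Expression filtering** — call genes expressed at ≥ 0.5 FPKM/RPKM in
   at least one atlas dataset; restrict to protein-coding biotypes.
3. **Differential protein abundance** — per protein and fraction, fold as
   percent of wild type and a one-way two-group ANOVA p-value
   (equivalently the pooled-variance t-test), with protein→gene mapping
   and volcano coordinates clamped to |log2 fold| ≤ 6, −log10 p ≤ 4.
4. **Inverse-pair discovery** — pair a miRNA changed beyond the 75–125%
   band with candidate targets changed significantly (p < 0.05) beyond
   the same band in the opposite direction, in either fraction; conflicts
   are flagged, not vetoed. Co-targeting is summarized as a
   miRNA × miRNA shared-target matrix.
5. **Pathway over-representation** — upper-tail hypergeometric test of
   up-/down-regulated sets (> 2.0-fold / < 0.5-fold, p < 0.05) against
   the identified-protein background, minimum overlap 2, BH q-values.
6. **miR-CATCH quantification** — probe off-target screening by longest
   antiparallel complementary stretch (≤ 15 nt passes), comparative-Ct
   (ΔΔCt) mRNA enrichment, normalizer-free background-filtered miRNA
   enrichment with explicit not-amplified semantics, shared-site fold
   summation, and classification of captured miRNAs into
   predicted-and-enriched vs enriched-only parts.
7. **Interactome overlay** — annotate a protein-interaction edge list
   with expression tiers (log2 cutoff −1), MS detection and regulation
   calls; writes TSV + GML.
8. **Synthetic data** — a seeded generator that emulates every input
   with recorded planted truths (consensus sites, folds, inverse pairs,
   Ct-level enrichments), so the full pipeline is testable offline.

The central statistic of stage 4 is simple but strict: a pair
(miRNA *m*, gene *g*) is reported iff *g* has a consensus site for *m*,
fold(*m*) ∉ [75%, 125%] of wild type, and in ≥ 1 fraction
fold(*g*) ∉ [75%, 125%] with sign opposite to *m* and p < 0.05.

## Worked example

```r
library(mircircuits)

cfg <- simConfig(seed = 7, nGenes = 150, nSites = 60)
study <- simulateStudy(cfg)
study
#> SimulatedStudy (seed 7)
#>   predictions : 111 site rows, 3 tools
#>   atlas       : 150 genes, 3 datasets
#>   proteome    : 150 proteins x 16 runs
#>   ct table    : 9 assays
#>   planted     : 18 consensus sites, 17 inverse pairs

cons <- consensusSites(predictedSites(study@predictions))
de <- suppressWarnings(
  mapProteinsToGenes(differentialAbundance(study@proteome),
                     study@proteinMap))
pairs <- inversePairs(study@mirnaChanges, de, candidatesPerMirna(cons))
head(pairs, 3)
#>   mirna   gene             direction fractions_supporting conflicting_fraction
#> 1 miR-1 g00036 mirna_up_protein_down       membrane,whole
#> 2 miR-1 g00066 mirna_up_protein_down       membrane,whole
#> 3 miR-1 g00070 mirna_up_protein_down       membrane,whole
#>   protein_fold_percent    protein_p mirna_fold_percent
#> 1             26.17375 7.827865e-06                550
#> 2             32.65722 1.011344e-04                550
#> 3             34.97001 8.024439e-05                550

sharedTargets(pairs)
#>         miR-1 miR-133 miR-183 miR-96
#> miR-1       4       0       0      0
#> miR-133     0       3       0      0
#> miR-183     0       0       5      1
#> miR-96      0       0       1      5
```

Each pair row reads: miR-1 rose to 550% of wild type while the protein
for `g00036` fell to ~26% (p ≈ 8e-06) in both fractions — an inverse
relationship consistent with miR-1 repressing that gene. The
shared-target matrix shows per-miRNA target counts on the diagonal and
co-targeted genes off-diagonal (here miR-183 and miR-96 share one
target, as expected for clustered miRNAs with related seeds).

File-based inputs work the same way: `runPipeline(pipelineConfig(...))`
orchestrates the stages from TSV/GMT inputs (see
`writeSimulatedStudy()` for the dialects) and writes all stage outputs
plus an effective-configuration echo to an output directory.

## Vignette

`vignettes/mircircuits-methods.Rmd` documents the models and their
assumptions, every tunable threshold with its default and rationale,
the synthetic generator's noise model and what passing tests do and do
not demonstrate about real data, numerical edge-case handling, and known
limitations.
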