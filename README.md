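# m6Ashift

Where on a transcript N6-methyladenosine (m6A) sits matters: most m6A is
deposited near stop codons and in 3'UTRs, but a minority of genes carry it
in the 5'UTR, right where transcription starts. `m6Ashift` is an R
(Bioconductor-style) toolkit for asking what 5'UTR-specific m6A does to
chromatin and expression, given the standard outputs of upstream
processing: a gene annotation (GFF3/GTF), MACS2-style peak calls
(narrowPeak/BED) from meRIP-seq and histone ChIP-seq, a coverage track
(bedGraph), and an RPKM expression table.

The package

* classifies genes by the transcript region carrying their m6A peak
  *summits* and builds the five m6A-location groups (5'UTR, 3'UTR, both,
  only-5'UTR, only-3'UTR) plus the all-m6A group;
* computes TSS-anchored and gene-body-scaled metagene profiles of
  H3K4me3 coverage, per group, normalized to signal-per-million;
* quantifies the **summit shift** — with the aggregate profile binned at
  10 bp downstream of the TSS, the group summit is the argmax bin
  midpoint `s(G)`, and the shift between groups A and B is
  `Δ = s(A) − s(B)` (positive: A's H3K4me3 sits farther downstream), with
  a gene-resampling bootstrap CI;
* computes the association statistics: Pearson correlation of
  `log2(5'UTR fold enrichment)` with `log2(RPKM + 1)` and with the
  per-gene TSS-to-summit distance; pairwise Welch t-tests of expression
  between groups; marked-gene overlap percentages against a seeded
  random-gene control; and the writer-loss fraction between two peak
  sets;
* ships a synthetic-data generator (`simulateDataset()`) that emits all
  input formats plus a truth manifest with planted effect sizes, so the
  whole pipeline is testable offline against known ground truth.

## Worked example

Simulate a dataset with the default planted structure (60-bp mean shift,
negative enrichment-expression coupling), then run the analysis:

```r
library(m6Ashift)

sim    <- simulateDataset(simConfig(nGenes = 800, seed = 42))
m6a    <- filterPeaks(sim$m6a)          # FDR < 0.01, fold enrichment > 1.5
groups <- buildGroups(m6a, sim$catalog)
groups
#> GroupTable over a universe of 800 genes
#>   G_5UTR  218
#>   G_53    97
#>   G_5only 121
#>   G_3only 304
#>   G_3UTR  401
#>   G_m6A   522

p5 <- tssProfile(sim$coverage, groupGenes(groups, "G_5only"), sim$catalog)
p3 <- tssProfile(sim$coverage, groupGenes(groups, "G_3only"), sim$catalog)
groupShift(p5, p3, 1000, c("m6A_5", "m6A_3"))
#> ShiftResult: m6A_5 summit 365 bp vs m6A_3 summit 305 bp downstream of TSS
#>   shift = +60 bp (bin width 10 bp)

enrichmentExpressionCorr(groups, sim$expression)
#> Pearson r = -0.3519 (n = 121, two-sided p = 7.55e-05)

d <- geneSummitDistance(sim$catalog, groupGenes(groups, "G_5only"),
                        filterPeaks(sim$h3k4me3), groups = groups)
enrichmentShiftCorr(d)
#> Pearson r = 0.7708 (n = 121, two-sided p = 4.73e-25)
```

Reading: genes methylated only in the 5'UTR carry their aggregate H3K4me3
summit 60 bp farther downstream of the TSS than genes methylated only in
the 3'UTR; stronger 5'UTR methylation goes with lower expression
(r < 0) and with a larger per-gene downstream summit distance (r > 0) —
exactly the structure the generator planted.

The same analyses run file-to-file through the pipeline front end:

```r
cfg <- runConfig(outDir = "out", seed = 1,
                 simulate = simConfig(nGenes = 800, seed = 1))
runPipeline("all", cfg)   # out/{simulate,classify,metagene,shift,correlate}/
```

or from a shell via the thin wrapper `inst/scripts/m6ashift-cli.R`.

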