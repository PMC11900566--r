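---
title: "Methods: region-resolved m6A classification and the H3K4me3 summit shift"
author: "m6Ashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-resolved m6A classification and the H3K4me3 summit shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

N6-methyladenosine (m6A) is usually deposited near stop codons and 3'UTRs;
a minority of transcripts carry it in the 5'UTR, immediately downstream of
the transcription start site (TSS). `m6Ashift` implements the computational
side of asking what 5'UTR-specific m6A does to transcription: it classifies
genes by the transcript region carrying their m6A peaks, profiles the
active-chromatin mark H3K4me3 around the TSS per gene group, quantifies how
far downstream the aggregate H3K4me3 summit sits in each group, and
correlates 5'UTR m6A enrichment with expression and with the per-gene
summit distance. Inputs are the standard products of upstream processing —
a gene annotation (GFF3/GTF), MACS2-style peak calls (narrowPeak/BED) from
meRIP-seq and ChIP-seq, a coverage track (bedGraph), and an RPKM table.
Read alignment and peak calling are upstream of this package by design.

# Data model and conventions

All genomic intervals are held as `GenomicRanges` objects, i.e. 1-based,
closed intervals — the native convention of the R/Bioconductor stack this
package is built on. The 0-based half-open file formats (narrowPeak, BED,
bedGraph) are converted on read and write by the standard rules; GFF3/GTF
is already 1-based. Keeping the container's convention internally means
every interval operation (overlap, coverage, reduction) can be delegated
to `GenomicRanges`/`IRanges` without coordinate shims at each call.

One representative transcript is kept per gene: the isoform with the
longest genomic span, ties broken by the lexicographically smallest
transcript id. The longest isoform maximizes annotated UTR coverage, which
is what the region classification depends on; the choice is deterministic
and recorded in the catalog (`transcript_id` column). Genes lacking an
annotated 5'UTR or 3'UTR stay in the catalog (they can still receive CDS
peaks) but are excluded from the "all genes" baseline universe
(`allGenes()`), which requires at least 1 bp of both UTRs.

The TSS is the span start on the plus strand and the span end on the minus
strand; `tssOffset()` is signed, with positive values downstream in the
direction of transcription. Every profile and distance in the package is
strand-aware through this one function.

# Peak-to-region assignment and gene groups

The assignment rule is summit-based: a peak belongs to the region (5'UTR,
CDS, 3'UTR) whose interval union contains its single-bp summit. A peak
whose summit falls in no annotated region is intergenic and carries no
gene. Summit assignment is unambiguous for peaks that span region
boundaries — any-overlap rules would double-assign them — and it matches
the summit-centric shift statistic used downstream. When overlapping genes
both contain a summit, the gene with the nearest TSS wins, then the
smaller gene id; opposite-strand overlaps are resolved the same way
because peaks are strandless.

Gene groups follow the strict reading of "only": `G_5only` requires every
peak summit of the gene to lie in the 5'UTR, so a CDS peak disqualifies a
gene from `G_5only` even though it never puts the gene in `G_3UTR`. The
per-gene region sets are retained in the `GroupTable`
(`perGeneRegions()`), so the looser reading (no 3'UTR peak) can be
recomputed without re-running assignment. The class validity enforces the
set identities (`G_53 = G_5UTR ∩ G_3UTR`, `G_5only ⊆ G_5UTR`,
disjointness of the two "only" groups, everything inside `G_m6A`) on
every constructed object.

Peak filtering applies the caller's reporting thresholds — FDR < 0.01 and
fold enrichment > 1.5, both strict — before any classification.
"Marked genes" for the histone overlap comparison are genes whose body
(TSS to TES) overlaps at least one peak interval by ≥ 1 bp; this is the
most common convention, and an optional promoter extension (default 0 bp)
is exposed for sensitivity analysis. The random-gene control draws, with a
fixed seed, `reps = 100` gene sets of the same size as the marked set from
the whole catalog; the mean of the per-draw percentages stabilizes what a
single random draw would estimate noisily.

# Metagene profiles and the shift statistic

`tssProfile()` computes, per gene, the mean coverage in each strand-aware
10-bp bin downstream of the TSS (window 1000 bp by default), normalizes to
signal-per-million of the track's library size, and averages across genes.
The per-bin statistic is the mean over bin bp (not the max), the standard
metagene convention. There is no per-gene rescaling: absolute differences
in H3K4me3 level between groups remain visible, which the analysis relies
on. Genes shorter than the window contribute only the bins they cover, and
per-bin gene counts are kept; positions beyond a chromosome edge are
treated as missing, not as zero coverage. No smoothing is applied.
`bodyProfile()` additionally rescales each gene body to 100 bins with
fixed-width 50-bp flank bins, skipping (with a warning and a count) genes
shorter than the bin count.

The group summit is the argmax bin of the aggregate profile within the
search window (1000 bp by default; the interesting summits sit well below
400 bp), reported at the bin midpoint. With 10-bp bins this yields
positions like 315 or 375 bp. The midpoint convention is arbitrary but
must be fixed; whether published summit positions are bin starts,
midpoints or ends is generally unstated, and a one-bin tolerance absorbs
the difference. Ties break toward the TSS — the conservative direction,
since it can only shrink a claimed downstream shift. The shift between
groups A and B is `summit(A) − summit(B)` on the aggregate (mean)
profiles, not a difference of per-gene summit medians: the aggregate is
what metagene figures display, and it is robust to genes with weak
individual signal. Per-gene TSS-to-summit distances are computed
separately (`geneSummitDistance()`, nearest downstream summit within
2000 bp) for the enrichment-vs-shift correlation, where a per-gene
quantity is required.

Because the aggregate shift has no analytic error bar, a bootstrap
(`bootstrapShiftCi()`) resamples genes within each group with replacement
and reports the percentile 95% interval. Per-gene binned coverage is
computed once and resamples only re-average rows, so 200 resamples cost
little more than two profiles.

# Association statistics

Correlations are Pearson product-moment coefficients with two-sided
p-values from the t-transform with n − 2 degrees of freedom. Enrichment
and expression both enter on log2 scales (`log2(FE)`,
`log2(RPKM + 1)`): fold enrichments and expression are conventionally
displayed log-scaled and both are strongly right-skewed; a raw-scale
option is retained. A gene's m6A enrichment is the maximum fold
enrichment among its 5'UTR peaks — one value per gene is needed, and
"max" takes the strongest evidence of methylation.

Group-wise expression comparisons use the Welch (unequal-variance) flavor
of the t-test on `log2(RPKM + 1)`: group sizes and variances differ
substantially between the five m6A-location groups, and Welch is the safe
default; the classic equal-variance flavor is a flag, and the two agree
when sample variances and sizes match. Significance marks follow the
conventional thresholds (`**` < 0.01, `*` < 0.05, `NS`). Raw p-values are
reported without multiple-testing correction, matching how such panel
figures are annotated; a Benjamini–Hochberg column is available but off
by default.

# The synthetic-data generator

`simulateDataset()` emits a complete dataset in the standard formats plus
a truth manifest, so every stage is testable without downloads. What it
emulates, and the defaults (all configurable in `simConfig()`):

* **Gene models**: `nGenes` genes on one synthetic chromosome, spaced
  ≥ 2 kb apart, half on the minus strand so no strand-handling path goes
  untested. 5'UTR/CDS/3'UTR lengths are log-normal, centred on
  150/1100/220 bp with sdlog 0.35 — compact, plant-like gene structures.
* **m6A peaks**: each gene is assigned to `5only` (0.15), `3only` (0.35),
  `53` (0.15) or `none` (0.35); 3'UTR methylation dominates, 5'UTR
  methylation is the minority class, as in real methylomes. Summits are
  uniform inside the designated UTR. Fold enrichments are log-normal
  (median 3, sdlog 0.5) truncated below at 1.5, because real peak files
  are emitted by a caller that has already applied its fold-enrichment
  threshold; an optional decoy fraction adds sub-threshold peaks to
  exercise the filter.
* **H3K4me3**: one Gaussian coverage bump per gene (sd 75 bp, roughly the
  +1-nucleosome scale) over a uniform background (0.2 per bp), centred
  `310 + shiftBeta · log2(FE_5UTR) + Normal(0, 20)` bp downstream of the
  TSS — 310 bp is the baseline summit offset, the coupling applies to
  genes methylated in the 5'UTR, and the default `shiftBeta` is chosen via
  `shiftBetaFor(60)` so the planted mean group shift is exactly 60 bp,
  the package's default effect size. The matching narrowPeak summit sits
  exactly at the bump centre.
* **Expression**: `RPKM = 2^(3 + exprBeta · log2(FE_5UTR) + Normal(0, 0.8))`
  with `exprBeta = −0.6`, planting the negative coupling between 5'UTR
  methylation and abundance at a correlation strength (|r| ≈ 0.45)
  typical of published enrichment-vs-expression scatters.

Because fold enrichments are truncated, the planted mean shift uses the
truncated-normal mean of `log2 FE`; `plantedShift()` and `shiftBetaFor()`
do this arithmetic so planted and recovered shifts are directly
comparable. All randomness flows from one seed; outputs are
byte-reproducible, and `verifyManifest()` cross-checks every manifest gene
against the emitted files after a round trip through the package's own
readers.

What the generator does **not** emulate: read-level noise and peak-caller
artefacts (peaks are placed, not called), replicate structure, overlapping
or intron-containing gene models, mappability gaps, multi-chromosome
genomes, and any sequence content. Passing tests therefore demonstrate
that the estimators recover planted positional and correlational structure
under realistic noise — not that upstream peak calling is reliable.

# Test conditions and numerical choices

The statistical guarantees are exercised at fixed problem sizes chosen to
make sampling noise small relative to the tolerances while keeping the
default suite fast: shift recovery over planted shifts of 0/60/100/150 bp
at 1000 genes across 100 seeded runs (tolerance one 10-bp bin, ≥ 95%
required); correlation-sign recovery at 500 genes across 100 seeds; null
calibration (both couplings zero) across 500 seeds with the p < 0.05 rate
required inside [0.02, 0.08]; and oracle equivalence of the region
assignment and overlap arithmetic against brute-force linear scans on
1000 random fixtures. Degenerate inputs fail loudly: zero-variance
vectors, empty groups, all-zero profiles, overlapping coverage runs and
malformed annotation lines all raise typed errors rather than propagating
NaN.

Known limitations: summit positions are quantized to the bin grid, so
shifts smaller than half a bin are invisible by construction; the
nearest-TSS tie-break for overlapping genes is a heuristic; and the
aggregate-profile summit can sit one bin off the planted offset when the
per-gene center spread is large relative to the bump width, which the
one-bin tolerance acknowledges.
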