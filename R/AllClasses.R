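#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame Rle runValue runLength
#'   split queryHits subjectHits
#' @importFrom IRanges IRanges RleList
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end
#'   width strand findOverlaps coverage
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<-
#' @importFrom stats setNames rnorm runif rlnorm sd quantile
#' @importFrom utils head read.table write.table
NULL

# All genomic coordinates in this package are 1-based, closed intervals
# (the GRanges convention); 0-based half-open formats (narrowPeak, BED,
# bedGraph) are converted on read and write.

#' GeneCatalog: one representative transcript model per gene
#'
#' Holds, for every gene, a single representative transcript (the longest
#' isoform) with its genomic span, strand-aware transcription start site
#' (TSS), and the genomic intervals of its 5'UTR, CDS and 3'UTR (interval
#' lists, so multi-exon regions are kept as unions). Chromosome lengths are
#' carried alongside so coverage queries can be clipped.
#'
#' @slot spans A [GenomicRanges::GRanges] named by gene id with metadata
#'   columns `transcript_id` and `tss` (genomic bp of the TSS).
#' @slot utr5,cds,utr3 [GenomicRanges::GRangesList] objects named by gene
#'   id; elements may be empty when a transcript lacks that region.
#' @slot genomeSizes Named numeric vector of chromosome lengths (bp).
#'
#' @details On the plus strand the TSS equals the span start; on the minus
#' strand it equals the span end. Genes lacking either UTR are retained but
#' excluded from the "all genes" universe returned by [allGenes()].
#' @seealso [loadAnnotation()], [allGenes()], [tssOffset()]
#' @export
setClass("GeneCatalog",
  representation(
    spans = "GRanges",
    utr5 = "GRangesList",
    cds = "GRangesList",
    utr3 = "GRangesList",
    genomeSizes = "numeric"
  )
)

setValidity("GeneCatalog", function(object) {
  msg <- character()
  ids <- names(object@spans)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "spans must be uniquely named by gene_id")
  for (sl in c("utr5", "cds", "utr3")) {
    rl <- slot(object, sl)
    if (!identical(names(rl), ids))
      msg <- c(msg, sprintf("%s must be named identically to spans", sl))
  }
  chroms <- as.character(unique(seqnames(object@spans)))
  if (!all(chroms %in% names(object@genomeSizes)))
    msg <- c(msg, "every transcript chromosome must appear in genomeSizes")
  tss <- mcols(object@spans)$tss
  if (length(object@spans)) {
    plus <- as.character(strand(object@spans)) == "+"
    bad <- ifelse(plus, tss != start(object@spans), tss != end(object@spans))
    if (any(bad))
      msg <- c(msg, sprintf("TSS inconsistent with strand for: %s",
                            paste(head(ids[bad], 3), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' PeakSet: a labelled, sorted set of called peaks
#'
#' Wraps a [GenomicRanges::GRanges] of peak intervals with per-peak summit
#' (genomic bp), fold enrichment and q-value (FDR), as produced by MACS2
#' style peak callers and read from narrowPeak/BED files.
#'
#' @slot peaks A GRanges with metadata columns `name`, `summit`,
#'   `foldEnrichment`, `qvalue`; sorted by (chrom, start).
#' @slot sampleLabel Single string identifying the sample.
#' @seealso [readPeaks()], [filterPeaks()]
#' @export
setClass("PeakSet",
  representation(peaks = "GRanges", sampleLabel = "character")
)

setValidity("PeakSet", function(object) {
  msg <- character()
  p <- object@peaks
  need <- c("name", "summit", "foldEnrichment", "qvalue")
  if (!all(need %in% names(mcols(p))))
    return(sprintf("peaks must carry metadata columns: %s",
                   paste(need, collapse = ", ")))
  if (length(p)) {
    s <- mcols(p)$summit
    if (any(s < start(p) | s > end(p)))
      msg <- c(msg, "every summit must lie within its peak interval")
    if (any(is.na(mcols(p)$foldEnrichment)) ||
        any(mcols(p)$foldEnrichment < 0))
      msg <- c(msg, "foldEnrichment must be non-missing and >= 0")
    q <- mcols(p)$qvalue
    if (any(q < 0 | q > 1)) msg <- c(msg, "qvalue must lie in [0, 1]")
    o <- order(as.character(seqnames(p)), start(p))
    if (!identical(o, seq_along(p)))
      msg <- c(msg, "peaks must be sorted by (chrom, start)")
  }
  if (length(object@sampleLabel) != 1L)
    msg <- c(msg, "sampleLabel must be a single string")
  if (length(msg)) msg else TRUE
})

#' CoverageTrack: run-length encoded genome-wide signal
#'
#' Per-chromosome run-length encoded, non-negative signal (e.g. H3K4me3
#' ChIP-seq coverage), with the library size (total signal in
#' value-by-bp units) retained so profiles can be normalized to
#' signal-per-million lazily at profiling time.
#'
#' @slot cov An [IRanges::RleList], one run-length vector per chromosome.
#' @slot librarySize Total signal, `sum(value * run length)` over all runs.
#' @seealso [readCoverage()], [tssProfile()], [bodyProfile()]
#' @export
setClass("CoverageTrack",
  representation(cov = "RleList", librarySize = "numeric")
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  vals <- unlist(lapply(object@cov, runValue), use.names = FALSE)
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
    msg <- c(msg, "coverage values must be finite and >= 0")
  if (length(object@librarySize) != 1L || object@librarySize < 0)
    msg <- c(msg, "librarySize must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' GroupTable: m6A-location gene groups
#'
#' The five m6A-location gene groups plus the "any m6A" group, derived
#' from summit-based peak-to-region assignment:
#' \describe{
#'   \item{G_5UTR}{genes with at least one m6A peak summit in the 5'UTR}
#'   \item{G_3UTR}{likewise for the 3'UTR}
#'   \item{G_53}{genes with summits in both UTRs (`G_5UTR` intersect `G_3UTR`)}
#'   \item{G_5only}{genes whose every peak summit is in the 5'UTR}
#'   \item{G_3only}{genes whose every peak summit is in the 3'UTR}
#'   \item{G_m6A}{genes with at least one peak summit anywhere on the transcript}
#' }
#'
#' @slot groups Named list of character vectors of gene ids.
#' @slot universe Character vector: all genes in the catalog.
#' @slot perGene A data.frame (gene_id, regions, n_peaks, best_utr5_fe)
#'   recording, per m6A gene, the comma-joined set of regions hit, the
#'   number of assigned peaks, and the strongest 5'UTR fold enrichment
#'   (NA when the gene has no 5'UTR peak) — enough to recompute looser
#'   group definitions downstream.
#' @seealso [buildGroups()], [groupGenes()]
#' @export
setClass("GroupTable",
  representation(groups = "list", universe = "character",
                 perGene = "data.frame")
)

.GROUP_LABELS <- c("G_5UTR", "G_53", "G_5only", "G_3only", "G_3UTR", "G_m6A")

setValidity("GroupTable", function(object) {
  msg <- character()
  g <- object@groups
  if (!all(.GROUP_LABELS %in% names(g)))
    return(sprintf("groups must contain: %s",
                   paste(.GROUP_LABELS, collapse = ", ")))
  if (!all(g$G_5only %in% g$G_5UTR))
    msg <- c(msg, "G_5only must be a subset of G_5UTR")
  if (!all(g$G_3only %in% g$G_3UTR))
    msg <- c(msg, "G_3only must be a subset of G_3UTR")
  if (!setequal(g$G_53, intersect(g$G_5UTR, g$G_3UTR)))
    msg <- c(msg, "G_53 must equal G_5UTR intersect G_3UTR")
  if (length(intersect(g$G_5only, g$G_3UTR)))
    msg <- c(msg, "G_5only and G_3UTR must be disjoint")
  if (length(intersect(g$G_3only, g$G_5UTR)))
    msg <- c(msg, "G_3only and G_5UTR must be disjoint")
  if (!all(unlist(g[setdiff(.GROUP_LABELS, "G_m6A")]) %in% g$G_m6A))
    msg <- c(msg, "every group must be a subset of G_m6A")
  if (!all(g$G_m6A %in% object@universe))
    msg <- c(msg, "G_m6A must be a subset of the universe")
  if (length(msg)) msg else TRUE
})

#' Profile: an aggregate (metagene) signal profile
#'
#' Mean per-million-normalized signal per bin, averaged over a gene set,
#' either anchored at the TSS at fixed bp resolution (`TSS_ANCHORED`) or
#' with gene bodies rescaled to a fixed number of bins plus fixed-width
#' flanks (`BODY_SCALED`).
#'
#' @slot mode Either `"TSS_ANCHORED"` or `"BODY_SCALED"`.
#' @slot binEdges Numeric vector of bin edges, length `nbins + 1`. For
#'   TSS-anchored profiles these are bp downstream of the TSS; for
#'   body-scaled profiles, a composite axis (negative bp = upstream flank,
#'   `[0, nBodyBins]` = scaled body, then downstream flank bp offset by
#'   `nBodyBins`).
#' @slot values Mean normalized signal per bin (signal per million per bp).
#' @slot nGenesPerBin Number of genes contributing to each bin.
#' @slot nGenes Number of genes in the profiled set.
#' @slot binBp Bin width in bp (TSS-anchored mode).
#' @slot metadata List of profiling parameters (normalization, window,
#'   skipped genes, ...).
#' @seealso [tssProfile()], [bodyProfile()], [groupSummit()]
#' @export
setClass("Profile",
  representation(mode = "character", binEdges = "numeric",
                 values = "numeric", nGenesPerBin = "integer",
                 nGenes = "integer", binBp = "numeric", metadata = "list")
)

setValidity("Profile", function(object) {
  msg <- character()
  if (!object@mode %in% c("TSS_ANCHORED", "BODY_SCALED"))
    msg <- c(msg, "mode must be TSS_ANCHORED or BODY_SCALED")
  if (length(object@values) != length(object@binEdges) - 1L)
    msg <- c(msg, "length(values) must equal length(binEdges) - 1")
  if (length(object@nGenesPerBin) != length(object@values))
    msg <- c(msg, "nGenesPerBin must align with values")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "profile values must be >= 0")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ShiftResult: aggregate summit positions of two groups and their shift
#'
#' @slot summitA,summitB Aggregate H3K4me3 summit positions (bp downstream
#'   of the TSS, reported at bin midpoints) for the two gene groups.
#' @slot shift `summitA - summitB` in bp; positive means group A's summit
#'   lies farther downstream.
#' @slot binBp Profile bin width (bp); the shift is a multiple of it.
#' @slot groupLabels Character vector of length 2, the two group names.
#' @seealso [groupShift()], [bootstrapShiftCi()]
#' @export
setClass("ShiftResult",
  representation(summitA = "numeric", summitB = "numeric",
                 shift = "numeric", binBp = "numeric",
                 groupLabels = "character")
)

setValidity("ShiftResult", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@shift, object@summitA - object@summitB)))
    msg <- c(msg, "shift must equal summitA - summitB")
  if (abs(object@shift / object@binBp -
          round(object@shift / object@binBp)) > 1e-8)
    msg <- c(msg, "shift must be an integer multiple of binBp")
  if (length(object@groupLabels) != 2L)
    msg <- c(msg, "groupLabels must have length 2")
  if (length(msg)) msg else TRUE
})
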