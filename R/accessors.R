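#' @describeIn GeneCatalog-class Gene ids (names of the spans).
#' @param x,object A `GeneCatalog`.
#' @export
setMethod("geneIds", "GeneCatalog", function(x) names(x@spans))

#' @describeIn GeneCatalog-class Representative-transcript spans.
#' @export
setMethod("spans", "GeneCatalog", function(x) x@spans)

#' @describeIn GeneCatalog-class Named vector of TSS genomic coordinates.
#' @export
setMethod("tss", "GeneCatalog", function(x) {
  stats::setNames(mcols(x@spans)$tss, names(x@spans))
})

#' @describeIn GeneCatalog-class 5'UTR intervals per gene.
#' @export
setMethod("utr5", "GeneCatalog", function(x) x@utr5)

#' @describeIn GeneCatalog-class CDS intervals per gene.
#' @export
setMethod("cds", "GeneCatalog", function(x) x@cds)

#' @describeIn GeneCatalog-class 3'UTR intervals per gene.
#' @export
setMethod("utr3", "GeneCatalog", function(x) x@utr3)

#' @describeIn GeneCatalog-class Chromosome lengths.
#' @export
setMethod("genomeSizes", "GeneCatalog", function(x) x@genomeSizes)

#' @describeIn GeneCatalog-class Number of genes.
#' @export
setMethod("length", "GeneCatalog", function(x) length(x@spans))

setMethod("show", "GeneCatalog", function(object) {
  n <- length(object@spans)
  both <- length(allGenes(object))
  cat(sprintf(
    "GeneCatalog with %d genes on %d chromosome(s)\n  %d genes carry both a 5'UTR and a 3'UTR\n",
    n, length(object@genomeSizes), both))
})

#' All-genes universe: genes with both UTRs annotated
#'
#' The comparison universe used for metagene baselines and random-gene
#' controls: genes whose representative transcript has at least 1 bp of
#' annotated 5'UTR *and* 3'UTR.
#'
#' @param catalog A `GeneCatalog`.
#' @return Character vector of gene ids.
#' @export
allGenes <- function(catalog) {
  stopifnot(is(catalog, "GeneCatalog"))
  ids <- geneIds(catalog)
  has5 <- lengths(catalog@utr5) > 0L
  has3 <- lengths(catalog@utr3) > 0L
  ids[has5 & has3]
}

#' @describeIn PeakSet-class The peaks as a GRanges.
#' @param x,object A `PeakSet`.
#' @export
setMethod("peaks", "PeakSet", function(x) x@peaks)

#' @describeIn PeakSet-class Sample label.
#' @export
setMethod("sampleLabel", "PeakSet", function(x) x@sampleLabel)

#' @describeIn PeakSet-class Number of peaks.
#' @export
setMethod("length", "PeakSet", function(x) length(x@peaks))

setMethod("show", "PeakSet", function(object) {
  p <- object@peaks
  cat(sprintf("PeakSet '%s': %d peaks", object@sampleLabel, length(p)))
  if (length(p))
    cat(sprintf(" | fold enrichment %.2f-%.2f | min qvalue %.3g",
                min(mcols(p)$foldEnrichment), max(mcols(p)$foldEnrichment),
                min(mcols(p)$qvalue)))
  cat("\n")
})

#' @describeIn CoverageTrack-class Total signal (value x bp).
#' @param x,object A `CoverageTrack`.
#' @export
setMethod("librarySize", "CoverageTrack", function(x) x@librarySize)

#' @describeIn CoverageTrack-class Chromosome lengths covered.
#' @export
setMethod("genomeSizes", "CoverageTrack", function(x) {
  vapply(x@cov, length, numeric(1))
})

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack over %d chromosome(s), library size %.4g\n",
              length(object@cov), object@librarySize))
})

#' @describeIn GroupTable-class Genes in one group.
#' @param x,object A `GroupTable`.
#' @param label Group label.
#' @export
setMethod("groupGenes", "GroupTable", function(x, label) {
  label <- match.arg(label, .GROUP_LABELS)
  x@groups[[label]]
})

#' @describeIn GroupTable-class Sizes of all groups.
#' @export
setMethod("groupSizes", "GroupTable", function(x) {
  vapply(x@groups[.GROUP_LABELS], length, integer(1))
})

#' @describeIn GroupTable-class Universe gene ids.
#' @export
setMethod("geneIds", "GroupTable", function(x) x@universe)

setMethod("show", "GroupTable", function(object) {
  sz <- groupSizes(object)
  cat(sprintf("GroupTable over a universe of %d genes\n",
              length(object@universe)))
  cat(paste(sprintf("  %-7s %d", names(sz), sz), collapse = "\n"), "\n")
})

#' @describeIn Profile-class Mean normalized signal per bin.
#' @param x,object A `Profile`.
#' @export
setMethod("profileValues", "Profile", function(x) x@values)

#' @describeIn Profile-class Bin edges.
#' @export
setMethod("binEdges", "Profile", function(x) x@binEdges)

setMethod("show", "Profile", function(object) {
  cat(sprintf("%s Profile: %d bins, %d genes, peak value %.4g\n",
              object@mode, length(object@values), object@nGenes,
              max(object@values, na.rm = TRUE)))
})

setMethod("show", "ShiftResult", function(object) {
  cat(sprintf(
    "ShiftResult: %s summit %g bp vs %s summit %g bp downstream of TSS\n  shift = %+g bp (bin width %g bp)\n",
    object@groupLabels[1], object@summitA,
    object@groupLabels[2], object@summitB,
    object@shift, object@binBp))
})

#' @describeIn ShiftResult-class The shift in bp (`summitA - summitB`).
#' @param x A `ShiftResult`.
#' @export
shiftBp <- function(x) {
  stopifnot(is(x, "ShiftResult"))
  x@shift
}

#' @describeIn ShiftResult-class Both group summit positions (bp downstream
#'   of the TSS), named by group label.
#' @export
summitPositions <- function(x) {
  stopifnot(is(x, "ShiftResult"))
  stats::setNames(c(x@summitA, x@summitB), x@groupLabels)
}
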