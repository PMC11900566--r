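#' Gene identifiers in a catalog or group table
#' @param x A `GeneCatalog` or `GroupTable`.
#' @return Character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Transcription start sites
#' @param x A `GeneCatalog`.
#' @return Named numeric vector of genomic TSS coordinates (1-based bp).
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' Gene spans
#' @param x A `GeneCatalog`.
#' @return GRanges of representative-transcript spans, named by gene id.
#' @export
setGeneric("spans", function(x) standardGeneric("spans"))

#' Region interval lists
#' @param x A `GeneCatalog`.
#' @return GRangesList named by gene id.
#' @export
setGeneric("utr5", function(x) standardGeneric("utr5"))

#' @rdname utr5
#' @export
setGeneric("utr3", function(x) standardGeneric("utr3"))

#' @rdname utr5
#' @export
setGeneric("cds", function(x) standardGeneric("cds"))

#' Chromosome lengths
#' @param x A `GeneCatalog` or `CoverageTrack`.
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
setGeneric("genomeSizes", function(x) standardGeneric("genomeSizes"))

#' Peaks as a GRanges
#' @param x A `PeakSet`.
#' @return GRanges with summit/foldEnrichment/qvalue metadata columns.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' Sample label of a peak set
#' @param x A `PeakSet`.
#' @return Single string.
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' Total signal of a coverage track
#' @param x A `CoverageTrack`.
#' @return Total signal in value-by-bp units.
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' Member genes of one m6A-location group
#' @param x A `GroupTable`.
#' @param label One of `"G_5UTR"`, `"G_53"`, `"G_5only"`, `"G_3only"`,
#'   `"G_3UTR"`, `"G_m6A"`.
#' @return Character vector of gene ids.
#' @export
setGeneric("groupGenes", function(x, label) standardGeneric("groupGenes"))

#' Sizes of all m6A-location groups
#' @param x A `GroupTable`.
#' @return Named integer vector.
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' Profile values and bin edges
#' @param x A `Profile`.
#' @return Numeric vector.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname profileValues
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
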